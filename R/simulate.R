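#' Default module-size landscape for the synthetic cohort
#'
#' Seventeen module sizes decreasing from 272 to 18 proteins, summing to
#' 1675 so that a 1800-protein proteome retains 125 unassigned background
#' proteins.
#'
#' @return integer vector of length 17.
#' @export
defaultModuleSizes <- function() {
  c(272L, 212L, 180L, 159L, 140L, 129L, 110L, 90L, 75L, 62L,
    56L, 48L, 40L, 34L, 28L, 22L, 18L)
}

.defaultEffects <- function(nModules, caseGroups) {
  eff <- matrix(0, nModules, length(caseGroups),
                dimnames = list(sprintf("M%02d", seq_len(nModules)),
                                caseGroups))
  # first case group: 13 dysregulated modules, mostly down-shifted
  down <- c(1, 3, 4, 6, 7, 9, 10, 11); down <- down[down <= nModules]
  up   <- c(2, 5, 13, 16, 17);         up   <- up[up <= nModules]
  mag  <- function(i) 0.4 + 0.4 * ((i * 7L) %% 5L) / 4   # 0.4 .. 0.8, fixed
  if (length(caseGroups) >= 1L) {
    eff[down, 1L] <- -vapply(down, mag, 1)
    eff[up, 1L]   <-  vapply(up, mag, 1)
  }
  # second case group: 9 dysregulated modules, weaker contrast
  if (length(caseGroups) >= 2L) {
    tdp <- intersect(c(1, 2, 3, 4, 5, 7, 10, 13, 16), seq_len(nModules))
    eff[tdp, 2L] <- sign(eff[tdp, 1L]) * 0.6 * vapply(tdp, mag, 1)
  }
  eff
}

.defaultCelltypeMap <- function(nModules) {
  map <- rep(NA_character_, nModules)
  names(map) <- sprintf("M%02d", seq_len(nModules))
  assigned <- c(M01 = "excitatory_neurons", M02 = "astrocytes",
                M03 = "excitatory_neurons", M04 = "excitatory_neurons",
                M05 = "endothelial", M06 = "inhibitory_neurons",
                M07 = "microglia", M09 = "oligodendrocytes",
                M10 = "OPCs", M13 = "astrocytes")
  keep <- intersect(names(assigned), names(map))
  map[keep] <- assigned[keep]
  map
}

#' Configuration of the synthetic proteomics cohort
#'
#' Defines the generative model for a three-group brain-tissue cohort
#' (two case groups plus controls) with proteins organised into planted
#' co-abundance modules. Protein log2 abundance follows a one-factor-per-
#' module model: \eqn{x_{ps} = b_p + L f_{m(p),s} + \delta_{m(p),g(s)} +
#' \epsilon_{ps}} with per-module Gaussian factors \eqn{f}, loading
#' \eqn{L}, planted per-module group shifts \eqn{\delta} (log2 scale) and
#' i.i.d. noise. Proteins expand into peptides with fixed lognormal
#' ionization multipliers, splits across chromatographic fractions and
#' multiplicative peptide-level noise.
#'
#' @param n_control number of control samples.
#' @param n_per_case named integer vector of case-group sizes; the names
#'   are the group tokens (default `c(tau = 6, tdp = 15)`).
#' @param n_proteins proteome size.
#' @param module_sizes integer vector of planted module sizes (decreasing;
#'   must sum to at most `n_proteins`).
#' @param loading factor loading in \[0, 1\] shared by all module members.
#' @param factor_sd standard deviation of the per-module subject factor on
#'   the log2 scale (the amplitude of between-subject co-regulation); the
#'   factor contribution to a member protein is `loading * factor_sd` per
#'   standard deviation, so the within-module correlation is governed by
#'   `loading * factor_sd` relative to `noise_sd`.
#' @param noise_sd standard deviation of protein-level log2 noise.
#' @param effect_jitter between-subject variability of the planted module
#'   effects: the shift applied to module m in case sample s is
#'   `delta_m * (1 + effect_jitter * z_{m,s})`, so dysregulation is not a
#'   rigid group offset and effect patterns decorrelate across modules.
#' @param module_effects numeric matrix (modules x case groups) of signed
#'   log2 abundance shifts relative to control; `NULL` for the packaged
#'   default (13 modules shifted in the first case group, 9 in the second).
#' @param peptide_rate mean excess peptide count; peptides per protein are
#'   `1 + Poisson(peptide_rate)` (mode about 6 at the default 5).
#' @param fraction_count number of fractions peptides are spread over.
#' @param peptide_noise_sd multiplicative (log2) peptide-level noise sd.
#' @param bad_peptide_rate proportion of peptides given Q-values above
#'   0.01 in more than half of the samples (and thus filterable).
#' @param concordant_modules module labels whose planted effects are
#'   reproduced in the validation cohort; `NULL` for the default (9 of the
#'   13 first-case-group dysregulated modules).
#' @param hot_modules module labels that receive a planted hot chain of
#'   `hot_size` members with `hot_boost`-fold amplified effects.
#' @param hot_size,hot_boost size and effect amplification of hot chains.
#' @param celltype_modules named character vector module -> cell type
#'   (NA for none); `NULL` for the packaged default map over 7 CNS types.
#' @param dropout proportion of discovery proteins absent from the
#'   validation cohort (the cohorts' universes only partially overlap).
#' @param validation_snr signal-to-noise multiplier converting a planted
#'   log2 effect into the mean z-score of the validation cohort.
#'
#' @return a `SimConfig` object (validated list).
#' @seealso [simulatePeptideReport()], [simulateValidationStats()]
#' @export
simConfig <- function(n_control = 5L,
                      n_per_case = c(tau = 6L, tdp = 15L),
                      n_proteins = 1800L,
                      module_sizes = defaultModuleSizes(),
                      loading = 0.9,
                      factor_sd = 0.45,
                      noise_sd = 0.15,
                      module_effects = NULL,
                      effect_jitter = 0.3,
                      peptide_rate = 5,
                      fraction_count = 3L,
                      peptide_noise_sd = 0.15,
                      bad_peptide_rate = 0.05,
                      concordant_modules = NULL,
                      hot_modules = c("M03", "M04", "M06", "M10"),
                      hot_size = 6L,
                      hot_boost = 2,
                      celltype_modules = NULL,
                      dropout = 0.035,
                      validation_snr = 4) {
  if (is.null(names(n_per_case)))
    names(n_per_case) <- paste0("case", seq_along(n_per_case))
  nm <- length(module_sizes)
  labels <- sprintf("M%02d", seq_len(nm))
  if (any(module_sizes <= 0))
    stop("module sizes must be strictly positive")
  if (sum(module_sizes) > n_proteins)
    stop("sum of module sizes exceeds the proteome size")
  if (loading < 0 || loading > 1) stop("loading must lie in [0, 1]")
  if (factor_sd <= 0) stop("factor_sd must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (bad_peptide_rate < 0 || bad_peptide_rate > 1)
    stop("bad_peptide_rate must lie in [0, 1]")
  if (is.null(module_effects))
    module_effects <- .defaultEffects(nm, names(n_per_case))
  module_effects <- as.matrix(module_effects)
  if (nrow(module_effects) != nm ||
      ncol(module_effects) != length(n_per_case))
    stop("module_effects must be modules x case-groups")
  dimnames(module_effects) <- list(labels, names(n_per_case))
  if (is.null(concordant_modules)) {
    dys <- labels[module_effects[, 1L] != 0]
    concordant_modules <- head(dys, 9L)
  }
  if (!all(concordant_modules %in% labels))
    stop("unknown module label in concordant_modules")
  hot_modules <- intersect(hot_modules, labels)
  if (is.null(celltype_modules)) celltype_modules <- .defaultCelltypeMap(nm)
  cfg <- list(n_control = as.integer(n_control),
              n_per_case = n_per_case,
              n_proteins = as.integer(n_proteins),
              module_sizes = as.integer(module_sizes),
              module_labels = labels,
              loading = loading, factor_sd = factor_sd,
              noise_sd = noise_sd,
              module_effects = module_effects,
              effect_jitter = effect_jitter,
              peptide_rate = peptide_rate,
              fraction_count = as.integer(fraction_count),
              peptide_noise_sd = peptide_noise_sd,
              bad_peptide_rate = bad_peptide_rate,
              concordant_modules = concordant_modules,
              hot_modules = hot_modules,
              hot_size = as.integer(hot_size), hot_boost = hot_boost,
              celltype_modules = celltype_modules,
              dropout = dropout, validation_snr = validation_snr)
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_proteins, "proteins,",
      length(x$module_sizes), "planted modules (",
      max(x$module_sizes), "..", min(x$module_sizes), "),",
      x$n_control, "controls +",
      paste(sprintf("%d %s", x$n_per_case, names(x$n_per_case)),
            collapse = " + "), "cases\n")
  invisible(x)
}

.sampleFrame <- function(config) {
  groups <- c(rep("control", config$n_control),
              rep(names(config$n_per_case), config$n_per_case))
  data.frame(sample = sprintf("S%02d", seq_along(groups)),
             group = groups, stringsAsFactors = FALSE)
}

#' Generate a synthetic peptide-level quantification report
#'
#' Draws a full peptide report (sample, group, fraction, peptide, protein,
#' abundance, Q-value) from the generative model described in
#' [simConfig()], together with the ground truth needed to score every
#' downstream stage: the true protein-to-module map, the planted module
#' effects, hot-chain members, the concordant module set and the module
#' cell-type map.
#'
#' Peptide abundances are strictly positive; a `bad_peptide_rate` fraction
#' of peptides receive Q-values above 0.01 in more than half of the
#' samples (and are meant to be removed by [filterPeptides()]). The draw is
#' fully reproducible given `seed`.
#'
#' @param config a [simConfig()] object.
#' @param seed integer seed.
#' @return list with elements `report` (a `data.table`) and `truth` (a
#'   list: `module_of`, `effects`, `hot_members`, `concordant_modules`,
#'   `celltype_of_module`, `protein_log2`, the latent protein log2 matrix).
#' @export
simulatePeptideReport <- function(config, seed = 1L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(seed)
  samples <- .sampleFrame(config)
  ns <- nrow(samples)
  np <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(np))

  moduleOf <- rep(NA_character_, np)
  idx <- 1L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    moduleOf[idx:(idx + sz - 1L)] <- config$module_labels[m]
    idx <- idx + sz
  }
  names(moduleOf) <- proteins

  hotMembers <- list()
  for (hm in config$hot_modules) {
    mem <- proteins[!is.na(moduleOf) & moduleOf == hm]
    hotMembers[[hm]] <- head(mem, min(config$hot_size, length(mem)))
  }

  # latent protein log2 abundance
  baseline <- rnorm(np, mean = 13, sd = 1)
  factors <- matrix(rnorm(length(config$module_sizes) * ns), ncol = ns,
                    dimnames = list(config$module_labels, samples$sample))
  shift <- matrix(0, np, ns)
  effScale <- rep(1, np)
  for (hm in names(hotMembers))
    effScale[match(hotMembers[[hm]], proteins)] <- config$hot_boost
  inModule <- !is.na(moduleOf)
  mIdx <- match(moduleOf[inModule], config$module_labels)
  caseCols <- samples$group != "control"
  if (any(caseCols) && nrow(config$module_effects) > 0L) {
    effBySample <- config$module_effects[, samples$group[caseCols],
                                         drop = FALSE]
    # subject-level wobble of each module's dysregulation
    jit <- 1 + config$effect_jitter *
      matrix(rnorm(length(effBySample)), nrow(effBySample))
    shift[inModule, caseCols] <- (effBySample * jit)[mIdx, , drop = FALSE] *
      effScale[inModule]
  }
  x <- matrix(rnorm(np * ns, sd = config$noise_sd), np, ns) +
    baseline + shift
  x[inModule, ] <- x[inModule, ] +
    (config$loading * config$factor_sd) * factors[mIdx, , drop = FALSE]
  dimnames(x) <- list(proteins, samples$sample)

  # peptide expansion
  npep <- 1L + rpois(np, config$peptide_rate)
  pepProtein <- rep(proteins, npep)
  pepId <- paste0(pepProtein, "_pep",
                  unlist(lapply(npep, seq_len), use.names = FALSE))
  totalPep <- length(pepId)
  pepMult <- 2^rnorm(totalPep, mean = 0, sd = 1.5)

  # fraction split: a primary fraction, sometimes spilling into a second
  primary <- sample.int(config$fraction_count, totalPep, replace = TRUE)
  spills <- config$fraction_count > 1L &
    runif(totalPep) < 0.3
  secondary <- ifelse(primary < config$fraction_count,
                      primary + 1L, primary - 1L)
  fracRows <- data.table::data.table(
    pep = c(seq_len(totalPep), which(spills)),
    fraction = c(primary, secondary[spills]),
    weight = c(ifelse(spills, 0.7, 1), rep(0.3, sum(spills))))

  # assemble long table: (peptide x fraction) x samples
  protRow <- match(pepProtein, proteins)
  long <- fracRows[rep(seq_len(nrow(fracRows)), each = ns)]
  long[, sample := rep(samples$sample, times = nrow(fracRows))]
  long[, group := rep(samples$group, times = nrow(fracRows))]
  sampIdx <- match(long$sample, samples$sample)
  latent <- x[cbind(protRow[long$pep], sampIdx)]
  noise <- 2^rnorm(nrow(long), sd = config$peptide_noise_sd)
  long[, abundance := 2^latent * pepMult[pep] * weight * noise]
  long[, peptide := pepId[pep]]
  long[, protein := pepProtein[pep]]
  long[, fraction := paste0("F", fraction)]

  # Q-values: bad peptides score poorly in a random majority of samples
  bad <- runif(totalPep) < config$bad_peptide_rate
  long[, qvalue := runif(.N, 0, 0.01)]
  if (any(bad)) {
    majority <- floor(ns / 2) + 1L
    badPairs <- data.table::rbindlist(lapply(which(bad), function(bp) {
      nbad <- sample(majority:ns, 1L)
      data.table::data.table(pep = bp,
                             sample = samples$sample[sample.int(ns, nbad)])
    }))
    idx <- long[badPairs, on = c("pep", "sample"), which = TRUE]
    idx <- idx[!is.na(idx)]
    long[idx, qvalue := runif(length(idx), 0.011, 0.5)]
  }

  report <- long[, list(sample, group, fraction, peptide, protein,
                        abundance, qvalue)]
  data.table::setorder(report, sample, fraction, peptide)

  truth <- list(module_of = moduleOf,
                effects = config$module_effects,
                effect_scale = setNames(effScale, proteins),
                hot_members = hotMembers,
                concordant_modules = config$concordant_modules,
                celltype_of_module = config$celltype_modules,
                protein_log2 = x,
                samples = samples)
  list(report = report, truth = truth)
}

#' Generate validation-cohort summary statistics
#'
#' Emits per-protein (p-value, log2FC) pairs for an independent validation
#' cohort at the statistics level. Proteins belonging to concordant modules
#' reproduce the sign of their planted discovery effect with small
#' p-values (mean z-score `validation_snr * |effect|`); all other proteins
#' draw uniform p-values and sign-random log2 fold changes. A `dropout`
#' fraction of the discovery universe is absent, emulating the partial
#' overlap of real cohort universes.
#'
#' @param truth ground truth from [simulatePeptideReport()].
#' @param config the [simConfig()] used to generate it.
#' @param seed integer seed.
#' @param case_group which case group's contrast the cohort replicates
#'   (default the first).
#' @return `data.frame` with columns `protein, log2fc, pvalue`.
#' @export
simulateValidationStats <- function(truth, config, seed = 2L,
                                    case_group = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(case_group)) case_group <- colnames(truth$effects)[1L]
  if (!case_group %in% colnames(truth$effects))
    stop("unknown case group: ", case_group)
  if (!all(config$concordant_modules %in% rownames(truth$effects)))
    stop("unknown module label in concordant_modules")
  set.seed(seed)
  proteins <- names(truth$module_of)
  keep <- runif(length(proteins)) >= config$dropout
  proteins <- proteins[keep]
  mod <- truth$module_of[proteins]
  eff <- rep(0, length(proteins))
  conc <- !is.na(mod) & mod %in% config$concordant_modules
  eff[conc] <- truth$effects[mod[conc], case_group] *
    truth$effect_scale[proteins[conc]]

  log2fc <- rnorm(length(proteins), mean = eff, sd = 0.3)
  pvalue <- runif(length(proteins))
  sig <- eff != 0
  if (any(sig)) {
    z <- rnorm(sum(sig), mean = config$validation_snr * abs(eff[sig]),
               sd = 1)
    pvalue[sig] <- 2 * pnorm(-abs(z))
    # fold change carries the planted sign unless the noisy draw flipped it
    log2fc[sig] <- sign(eff[sig]) * abs(log2fc[sig]) *
      ifelse(rnorm(sum(sig), mean = config$validation_snr *
                     abs(eff[sig])) > 0, 1, -1)
  }
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  data.frame(protein = proteins, log2fc = log2fc, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene-set collection
#'
#' Builds `n_terms` gene sets over the simulated proteome. A fraction
#' `alignment` of the terms coincide with planted modules (with a
#' `jitter` fraction of members swapped for random proteins); the
#' remaining terms are uniform random draws.
#'
#' @param truth ground truth from [simulatePeptideReport()].
#' @param n_terms number of gene sets (at least 1).
#' @param alignment proportion of terms aligned with planted modules.
#' @param jitter fraction of an aligned term's members replaced by random
#'   proteins.
#' @param size_range size range of the random (non-aligned) terms.
#' @param seed integer seed.
#' @return named list of character vectors (GMT-compatible; see
#'   [writeGmt()]).
#' @export
simulateAnnotationSets <- function(truth, n_terms = 50L, alignment = 0.5,
                                   jitter = 0.1, size_range = c(10L, 100L),
                                   seed = 3L) {
  if (n_terms < 1L) stop("n_terms must be at least 1")
  if (alignment < 0 || alignment > 1) stop("alignment must lie in [0, 1]")
  set.seed(seed)
  proteins <- names(truth$module_of)
  modules <- rownames(truth$effects)
  nAligned <- round(alignment * n_terms)
  sets <- list()
  for (i in seq_len(n_terms)) {
    if (i <= nAligned) {
      m <- modules[1L + (i - 1L) %% length(modules)]
      members <- names(truth$module_of)[!is.na(truth$module_of) &
                                          truth$module_of == m]
      nswap <- round(jitter * length(members))
      if (nswap > 0) {
        out <- sample(members, nswap)
        pool <- setdiff(proteins, members)
        members <- c(setdiff(members, out), sample(pool, nswap))
      }
      nm <- sprintf("TERM%03d_%s", i, m)
    } else {
      sz <- size_range[1] + sample.int(size_range[2] - size_range[1] + 1L, 1L) - 1L
      members <- sample(proteins, sz)
      nm <- sprintf("TERM%03d_random", i)
    }
    attr(members, "description") <- "synthetic"
    sets[[nm]] <- members
  }
  sets
}

#' Packaged CNS cell-type marker set
#'
#' The seven-class central-nervous-system marker list used throughout the
#' cell-type enrichment stage: astrocytes (AGT, SLC4A4, SLC1A2),
#' endothelial cells (FLT1, DUSP1, NOSTRIN), excitatory neurons (SLC17A7),
#' inhibitory neurons (GAD1), microglia (APBB1IP, TYROBP),
#' oligodendrocytes (MOBP) and oligodendrocyte precursor cells (PCDH15,
#' PDGFRA). Marker lists are disjoint across cell types.
#'
#' @return named list of character vectors, one per cell type.
#' @export
cnsMarkerSet <- function() {
  list(astrocytes = c("AGT", "SLC4A4", "SLC1A2"),
       endothelial = c("FLT1", "DUSP1", "NOSTRIN"),
       excitatory_neurons = "SLC17A7",
       inhibitory_neurons = "GAD1",
       microglia = c("APBB1IP", "TYROBP"),
       oligodendrocytes = "MOBP",
       OPCs = c("PCDH15", "PDGFRA"))
}

#' Generate a synthetic cell-type expression table and marker set
#'
#' Builds a gene-by-cell-type mean-expression table covering the simulated
#' proteome plus the canonical CNS markers of [cnsMarkerSet()]. Declared
#' markers are dominantly expressed in their own cell type (their
#' specificity approaches `dominance`); proteins belonging to modules with
#' a mapped driving cell type are moderately elevated in that type; all
#' other genes are near-uniform. The returned marker set augments the
#' canonical list with `n_marker_proteins` synthetic proteins per cell
#' type drawn from the mapped modules, so markers also occur inside
#' modules.
#'
#' @param truth ground truth from [simulatePeptideReport()].
#' @param config the [simConfig()] used to generate it.
#' @param dominance target specificity of a marker in its own cell type.
#' @param module_dominance specificity of module-driven (non-marker)
#'   proteins in the driving cell type.
#' @param n_marker_proteins synthetic marker proteins per cell type.
#' @param seed integer seed.
#' @return list with `expression` (gene x cell-type matrix) and `markers`
#'   (named list per cell type).
#' @export
simulateCelltypeInputs <- function(truth, config, dominance = 0.8,
                                   module_dominance = 0.5,
                                   n_marker_proteins = 10L, seed = 4L) {
  set.seed(seed)
  canon <- cnsMarkerSet()
  types <- names(canon)
  if (length(types) < 2L) stop("at least 2 cell types required")
  k <- length(types)
  genes <- c(names(truth$module_of), unlist(canon, use.names = FALSE))
  expr <- matrix(runif(length(genes) * k, 0.8, 1.2), ncol = k,
                 dimnames = list(genes, types))

  domValue <- function(d) d * (k - 1) / (1 - d)  # own-type level vs base 1
  for (ct in types)
    expr[canon[[ct]], ct] <- domValue(dominance) *
      runif(length(canon[[ct]]), 0.9, 1.1)

  markers <- canon
  ctOfModule <- truth$celltype_of_module
  for (m in names(ctOfModule)) {
    ct <- ctOfModule[[m]]
    if (is.na(ct) || !ct %in% types) next
    members <- names(truth$module_of)[!is.na(truth$module_of) &
                                        truth$module_of == m]
    expr[members, ct] <- domValue(module_dominance) *
      runif(length(members), 0.9, 1.1)
    pick <- head(members, n_marker_proteins)
    markers[[ct]] <- c(markers[[ct]], pick)
  }
  markers <- lapply(markers, unique)
  list(expression = expr, markers = markers)
}
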