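#' Read and write the package's plain-text interchange formats
#'
#' Peptide reports are long-format TSV with columns
#' `sample, group, fraction, peptide, protein, abundance, qvalue`; protein
#' matrices are TSV with proteins as rows (first column `protein`) plus a
#' sidecar `samples.tsv` mapping sample to group; contrast results are TSV
#' with columns `protein, log2fc, pvalue`. Gene sets use the standard GMT
#' dialect (name, description, members, tab-separated) and rankings the
#' two-column RNK dialect.
#'
#' @param path file path.
#' @param report a peptide report `data.frame`/`data.table`.
#' @name protmod-io
NULL

.peptideCols <- c("sample", "group", "fraction", "peptide", "protein",
                  "abundance", "qvalue")

#' @rdname protmod-io
#' @return `readPeptideReport()`: a `data.table` with the peptide-report
#'   columns, checked for key uniqueness and valid ranges.
#' @export
readPeptideReport <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  validatePeptideReport(dt)
}

#' @rdname protmod-io
#' @export
writePeptideReport <- function(report, path) {
  data.table::fwrite(data.table::as.data.table(report)[, .peptideCols,
                                                       with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

validatePeptideReport <- function(report) {
  dt <- data.table::as.data.table(report)
  missing <- setdiff(.peptideCols, names(dt))
  if (length(missing))
    stop("peptide report lacks column(s): ", paste(missing, collapse = ", "))
  if (anyNA(dt$abundance) || any(dt$abundance < 0))
    stop("peptide abundances must be non-negative and complete")
  if (any(dt$qvalue < 0 | dt$qvalue > 1))
    stop("q-values must lie in [0, 1]")
  if (anyDuplicated(dt, by = c("sample", "fraction", "peptide")))
    stop("duplicate (sample, fraction, peptide) records")
  dt
}

#' @rdname protmod-io
#' @param se a `SummarizedExperiment` protein matrix as produced by
#'   [rollupProteins()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_samples.tsv`.
#' @export
writeProteinMatrix <- function(se, prefix) {
  m <- SummarizedExperiment::assay(se, "abundance")
  dt <- data.table::data.table(protein = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, paste0(prefix, ".tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample = colnames(m),
                           group = as.character(se$group)),
    paste0(prefix, "_samples.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname protmod-io
#' @return `readProteinMatrix()`: a `SummarizedExperiment` with assay
#'   `"abundance"` and colData column `group`.
#' @export
readProteinMatrix <- function(prefix) {
  dt <- data.table::fread(paste0(prefix, ".tsv"), sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$protein
  sam <- data.table::fread(paste0(prefix, "_samples.tsv"), sep = "\t")
  m <- m[, sam$sample, drop = FALSE]
  makeProteinMatrix(m, setNames(sam$group, sam$sample))
}

makeProteinMatrix <- function(values, groupOf) {
  stopifnot(all(colnames(values) %in% names(groupOf)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(
      group = unname(groupOf[colnames(values)]),
      row.names = colnames(values)))
}

#' @rdname protmod-io
#' @param result a contrast result `data.frame` with columns
#'   `protein, log2fc, pvalue`.
#' @export
writeContrast <- function(result, path) {
  data.table::fwrite(result[, c("protein", "log2fc", "pvalue")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname protmod-io
#' @export
readContrast <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname protmod-io
#' @return `readGmt()`: a named list of character vectors with a
#'   `description` attribute per element.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line: ", substr(ln, 1, 60))
    members <- parts[-(1:2)]
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' @rdname protmod-io
#' @param sets named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname protmod-io
#' @param ranking named numeric vector (names are protein/gene tokens).
#' @export
writeRnk <- function(ranking, path) {
  data.table::fwrite(data.table::data.table(token = names(ranking),
                                            score = unname(ranking)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname protmod-io
#' @export
readRnk <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  setNames(dt[[2]], dt[[1]])
}

#' @rdname protmod-io
#' @param assignment a [ModuleAssignment-class].
#' @export
writeModuleAssignment <- function(assignment, path) {
  lab <- moduleLabels(assignment)
  data.table::fwrite(data.table::data.table(protein = names(lab),
                                            module = unname(lab)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname protmod-io
#' @export
readModuleAssignment <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  newModuleAssignment(setNames(dt$module, dt$protein))
}
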