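# TSV/CSV readers and writers for the pipeline's tabular interchange
# formats. Matrices travel as TSV with a probe-id first column and one
# column per sample, at full float precision.

#' Read a probes x samples matrix from TSV
#'
#' @param path TSV file: header row of sample ids, first column probe ids.
#' @return numeric matrix with dimnames.
#' @export
readMethylationMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) stop("empty or malformed matrix: ", path)
  ids <- as.character(dt[[1]])
  dup <- anyDuplicated(ids)
  if (dup) stop("duplicate probe id '", ids[dup], "' at line ", dup + 1)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix: ", path)
  rownames(m) <- ids
  m
}

#' Write a probes x samples matrix as TSV (lossless round-trip)
#'
#' @param path output file.
#' @param x numeric matrix with dimnames.
#' @return the path, invisibly.
#' @export
writeMethylationMatrix <- function(path, x) {
  dt <- data.table::as.data.table(x, keep.rownames = "probe_id")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a probe manifest as TSV
#'
#' @param path file path.
#' @return `readManifest`: a `DataFrame` with probe-id rownames.
#' @export
readManifest <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = "chr"))
  if (anyDuplicated(dt$probe_id)) stop("duplicate probe ids in manifest")
  man <- DataFrame(dt)
  rownames(man) <- man$probe_id
  man
}

#' @rdname readManifest
#' @param manifest a manifest `DataFrame`.
#' @export
writeManifest <- function(path, manifest) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a sample sheet as CSV
#'
#' @param path file path.
#' @return `readSampleSheet`: a `DataFrame` with sample-id rownames.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sheet")
  out <- DataFrame(df)
  rownames(out) <- df$sample_id
  if ("phenotype" %in% colnames(out))
    out$phenotype <- factor(out$phenotype, levels = c("control", "case"))
  if ("batch" %in% colnames(out)) out$batch <- factor(out$batch)
  out
}

#' @rdname readSampleSheet
#' @param sheet a sample sheet `DataFrame`.
#' @export
writeSampleSheet <- function(path, sheet) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a FilterLedger as JSON
#'
#' @param ledger a [FilterLedger-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLedger <- function(ledger, path) {
  jsonlite::write_json(list(
    initial_probes = ledger@initialProbes,
    excluded_by_category = as.list(ledger@excludedProbes),
    retained_probes = ledger@retainedProbes,
    initial_samples = ledger@initialSamples,
    excluded_samples_by_category = as.list(ledger@excludedSamples),
    retained_samples = ledger@retainedSamples),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Serialize an OPLSDAModel as JSON
#'
#' @param model an [OPLSDAModel-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOPLSDAModel <- function(model, path) {
  jsonlite::write_json(list(
    features = model@featureNames, center = model@center,
    scale = model@scale, w = model@w, p_load = model@pLoad,
    c_load = model@cLoad, W_o = model@Wo, P_o = model@Po,
    n_ortho = model@nOrtho, t_train = model@tTrain),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
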