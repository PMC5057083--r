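read_table_auto <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), comment.char = "#",
             check.names = FALSE)
}

as_num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read an annotated peak table
#'
#' Expects one row per detected peak with columns `sample_id`,
#' `metabolite_id`, `mode` (cation/anion), `peak_area`, and optionally
#' `sn_ratio` and `is_area` (the internal-standard peak area of the same
#' run). Unparseable S/N cells become missing, never zero.
#'
#' @param path TSV or CSV file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return Data frame of validated peak records.
#' @export
read_peak_table <- function(path, dialect = "auto") {
  df <- read_table_auto(path, dialect)
  need <- c("sample_id", "metabolite_id", "mode", "peak_area")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peak table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df$peak_area <- as_num_or_na(df$peak_area)
  if ("sn_ratio" %in% names(df)) df$sn_ratio <- as_num_or_na(df$sn_ratio)
  if ("is_area" %in% names(df)) df$is_area <- as_num_or_na(df$is_area)
  validate_peaks(df)
}

#' Read sample metadata
#'
#' Columns `sample_id`, `cohort` (training/validation), `group`
#' (case/control), optionally `age`, `sex` (F/M), `fasting`.
#'
#' @inheritParams read_peak_table
#' @export
read_sample_metadata <- function(path, dialect = "auto") {
  df <- read_table_auto(path, dialect)
  if (nrow(df) == 0) {
    warning("sample metadata file is empty: ", path)
    need <- c("sample_id", "cohort", "group")
    for (nm in setdiff(need, names(df))) df[[nm]] <- character(0)
  }
  validate_samples(df)
}

#' Read a calibration-standard table
#'
#' @inheritParams read_peak_table
#' @export
read_calibration <- function(path, dialect = "auto") {
  df <- read_table_auto(path, dialect)
  for (nm in intersect(c("standard_concentration", "standard_relative_area"),
                       names(df)))
    df[[nm]] <- as_num_or_na(df[[nm]])
  validate_standards(df)
}

#' Read a pathway-edge table into a directed metabolite graph
#'
#' Rows are substrate -> product edges with optional enzyme EC number and a
#' pathway label. Parallel edges with distinct EC numbers are allowed;
#' self-edges are rejected.
#'
#' @inheritParams read_peak_table
#' @return An [igraph::igraph] directed graph with edge attributes `ec` and
#'   `pathway`.
#' @export
read_pathway_graph <- function(path, dialect = "auto") {
  df <- read_table_auto(path, dialect)
  need <- c("substrate", "product")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pathway table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  self <- df$substrate == df$product
  if (any(self))
    stop("self-edge(s) not allowed: ", fmt_tokens(df$substrate[self]))
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  g
}

#' The bundled default pathway map
#'
#' Glycolysis (glucose to pyruvate, pyruvate to lactate and alanine), the
#' TCA cycle through malate, the urea cycle, glutamine/glutamate exchange and
#' the GABA shunt — the candidate space for substrate/product ratio indexes.
#'
#' @return Directed [igraph::igraph] graph.
#' @export
default_pathway_graph <- function() {
  path <- system.file("extdata", "pathway_energy_urea.tsv", package = "ratiodx",
                      mustWork = TRUE)
  read_pathway_graph(path)
}

#' Build a concentration matrix from peak records
#'
#' One cell per (sample, metabolite); a cell is missing when no record
#' exists. Every record's sample must appear in the metadata; a metabolite
#' with records under two modes for the same sample is rejected (ids must be
#' mode-reconciled upstream).
#'
#' @param peaks Validated peak records (see [read_peak_table()]).
#' @param samples Validated sample metadata; defines row order.
#' @param value_col Column holding the cell value (default `"peak_area"`).
#' @param provenance Provenance tag of the result.
#' @export
to_matrix <- function(peaks, samples, value_col = "peak_area",
                      provenance = "raw") {
  peaks <- validate_peaks(peaks)
  samples <- validate_samples(samples)
  orphan <- setdiff(peaks$sample_id, samples$sample_id)
  if (length(orphan))
    stop("peak record(s) for sample(s) absent from metadata: ",
         fmt_tokens(orphan))
  key <- paste(peaks$sample_id, peaks$metabolite_id, sep = "\r")
  if (anyDuplicated(key))
    stop("multiple records per (sample, metabolite) after mode merge: ",
         fmt_tokens(sub("\r", "/", key[duplicated(key)])))
  smp <- samples$sample_id
  met <- unique(peaks$metabolite_id)
  vals <- matrix(NA_real_, nrow = length(smp), ncol = length(met),
                 dimnames = list(smp, met))
  vals[cbind(match(peaks$sample_id, smp),
             match(peaks$metabolite_id, met))] <- peaks[[value_col]]
  metabolite_matrix(vals, provenance = provenance)
}

#' Write / read a metabolite matrix as TSV
#'
#' Samples as rows, metabolites as columns, `NA` for missing cells, values
#' written with 17 significant digits so a write/read round trip is
#' bit-identical. The provenance tag is kept in a leading comment line.
#'
#' @param x A `metabolite_matrix`.
#' @param path Output TSV path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "metabolite_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance=", x$provenance), con)
  writeLines(paste(c("sample_id", metabolite_ids(x)), collapse = "\t"), con)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  for (i in seq_len(nrow(x$values)))
    writeLines(paste(c(sample_ids(x)[i], fmt(x$values[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  provenance <- if (grepl("^# provenance=", first))
    sub("^# provenance=", "", first) else "raw"
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("matrix TSV lacks sample_id column")
  vals <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df$sample_id)
  metabolite_matrix(vals, provenance = provenance)
}

#' Write sample/peak/standard tables as TSV
#'
#' Plain TSV with header, `NA` for missing cells; the dialect every reader
#' of this package accepts.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
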