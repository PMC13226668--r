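#' Sparse UMI counts container
#'
#' A `counts_matrix` wraps a sparse genes-by-droplets UMI count matrix together
#' with its identifiers and the library it came from. Counts must be
#' non-negative; the raw I/O contract keeps them integral, while decontaminated
#' matrices (see [correct_counts()]) carry `integral = FALSE`.
#'
#' @param values a matrix coercible to [Matrix::dgCMatrix-class], genes in rows.
#' @param gene_ids,barcode_ids character vectors of unique identifiers matching
#'   the matrix dimensions.
#' @param library_id single string naming the sequencing library.
#' @param integral logical; require integer-valued entries (default `TRUE`).
#' @return an object of class `counts_matrix` with fields `values`, `gene_ids`,
#'   `barcode_ids`, `library_id`.
#' @export
counts_matrix <- function(values, gene_ids, barcode_ids, library_id,
                          integral = TRUE) {
  if (!methods::is(values, "sparseMatrix"))
    values <- Matrix::Matrix(values, sparse = TRUE)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != length(gene_ids))
    stop("counts_matrix: ", nrow(values), " rows but ", length(gene_ids),
         " gene ids", call. = FALSE)
  if (ncol(values) != length(barcode_ids))
    stop("counts_matrix: ", ncol(values), " columns but ", length(barcode_ids),
         " barcode ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(barcode_ids)) stop("duplicate barcode ids", call. = FALSE)
  x <- values@x
  if (length(x) && min(x) < 0) stop("negative counts", call. = FALSE)
  if (integral && length(x) && any(x != round(x)))
    stop("non-integral counts in an integer counts_matrix", call. = FALSE)
  dimnames(values) <- list(gene_ids, barcode_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         barcode_ids = as.character(barcode_ids),
         library_id = as.character(library_id), integral = integral),
    class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("<counts_matrix> library %s: %d genes x %d droplets, %d stored\n",
              x$library_id, nrow(x$values), ncol(x$values),
              length(x$values@x)))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$values)

#' Total UMIs per droplet
#' @param m a [counts_matrix()].
#' @return named numeric vector of per-droplet column sums.
#' @export
droplet_totals <- function(m) Matrix::colSums(m$values)

.read_tsv_quiet <- function(path, col_names, ...) {
  readr::read_tsv(path, col_names = col_names, show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a Matrix Market UMI bundle
#'
#' Reads a 10x-style directory holding `matrix.mtx` (coordinate triplets,
#' 1-based), `features.tsv` and `barcodes.tsv`, validating the header
#' dimensions against the sidecar tables.
#'
#' @param dir_path directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param library_id library name; defaults to the directory's basename.
#' @return a [counts_matrix()].
#' @export
read_counts_mtx <- function(dir_path, library_id = basename(dir_path)) {
  mtx <- file.path(dir_path, "matrix.mtx")
  fea <- file.path(dir_path, "features.tsv")
  bar <- file.path(dir_path, "barcodes.tsv")
  for (f in c(mtx, fea, bar))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed Matrix Market file ", mtx,
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  genes <- .read_tsv_quiet(fea, col_names = FALSE)[[1]]
  cells <- .read_tsv_quiet(bar, col_names = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop("dimension mismatch in ", dir_path, ": matrix.mtx declares ",
         nrow(m), " genes but features.tsv lists ", length(genes),
         call. = FALSE)
  if (ncol(m) != length(cells))
    stop("dimension mismatch in ", dir_path, ": matrix.mtx declares ",
         ncol(m), " droplets but barcodes.tsv lists ", length(cells),
         call. = FALSE)
  counts_matrix(m, genes, cells, library_id)
}

#' Write a Matrix Market UMI bundle
#'
#' Inverse of [read_counts_mtx()]: emits `matrix.mtx` (entries in column-major
#' order, 1-based coordinates), `features.tsv` and `barcodes.tsv`. Values are
#' written as plain decimals, so counts up to 2^53 round-trip exactly.
#'
#' @param m a [counts_matrix()].
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_counts_mtx <- function(m, dir_path) {
  stopifnot(inherits(m, "counts_matrix"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$values, file.path(dir_path, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(id = m$gene_ids),
                   file.path(dir_path, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(id = m$barcode_ids),
                   file.path(dir_path, "barcodes.tsv"), col_names = FALSE)
  invisible(dir_path)
}

#' Read a typed TSV table against a column schema
#'
#' @param path TSV file with a header row.
#' @param schema named character vector mapping required column names to types
#'   (`"character"`, `"double"`, `"integer"`). Unknown columns are preserved
#'   as character.
#' @return a tibble with the schema's columns typed; parse failures raise an
#'   error naming the offending row.
#' @export
read_table_schema <- function(path, schema) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  for (col in names(schema)) {
    if (schema[[col]] == "character") next
    conv <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(conv) & !is.na(raw[[col]]) |
                   is.na(raw[[col]]) | raw[[col]] == "NA")
    if (length(bad))
      stop("unparseable value in column '", col, "' at row ", bad[1],
           " of ", path, call. = FALSE)
    raw[[col]] <- if (schema[[col]] == "integer") as.integer(conv) else conv
  }
  raw
}

#' Read (or derive) donor metadata
#'
#' Donor records carry the glycemic state (`ND`/`PD`/`T2D`), HbA1c (%), age,
#' BMI, sex, ancestry and sequencing chemistry. When the `state` column is
#' absent it is assigned from HbA1c using the prediabetes band
#' (5.7% <= HbA1c <= 6.4%); below the band is `ND`, above is `T2D`.
#'
#' @param path donor TSV with header.
#' @param pd_band numeric length-2, the inclusive prediabetes HbA1c band.
#' @return tibble of donor records.
#' @export
read_donor_table <- function(path, pd_band = c(5.7, 6.4)) {
  d <- read_table_schema(path, c(donor_id = "character", hba1c = "double",
                                 age = "double", bmi = "double",
                                 sex = "character", ancestry = "character",
                                 chemistry = "character"))
  if (any(d$hba1c <= 0)) stop("hba1c must be positive", call. = FALSE)
  if (!"state" %in% names(d)) d$state <- assign_state(d$hba1c, pd_band)
  d$state <- factor(d$state, levels = c("ND", "PD", "T2D"))
  if (anyNA(d$state)) stop("unknown glycemic state label", call. = FALSE)
  tibble::as_tibble(d)
}

#' Glycemic state from HbA1c bands
#' @param hba1c numeric HbA1c percentages.
#' @param pd_band inclusive prediabetes band, default `c(5.7, 6.4)`.
#' @return character vector in `ND`/`PD`/`T2D`.
#' @export
assign_state <- function(hba1c, pd_band = c(5.7, 6.4)) {
  dplyr::case_when(hba1c < pd_band[1] ~ "ND",
                   hba1c <= pd_band[2] ~ "PD",
                   TRUE ~ "T2D")
}

#' Assemble a cohort bundle
#'
#' @param raw,filtered named lists of [counts_matrix()] per library; the
#'   filtered barcodes of a library must be a subset of its raw barcodes.
#' @param cells per-droplet metadata tibble (`barcode_id`, `library_id`, ...).
#' @param donors donor tibble (see [read_donor_table()]).
#' @param library_donors tibble `library_id`, `donor_id` mapping each library
#'   to its (possibly multiplexed) donors.
#' @return a list of class `cohort_bundle`.
#' @export
cohort_bundle <- function(raw, filtered, cells, donors, library_donors) {
  structure(list(raw = raw, filtered = filtered, cells = cells,
                 donors = donors, library_donors = library_donors),
            class = "cohort_bundle")
}

#' Validate a cohort bundle
#'
#' Checks every structural invariant downstream stages rely on and reports all
#' violations; an empty report means the bundle is consumable end to end.
#'
#' @param b a [cohort_bundle()].
#' @return tibble with columns `check`, `detail`; zero rows when valid.
#' @export
validate_cohort <- function(b) {
  viol <- list()
  note <- function(check, detail)
    viol[[length(viol) + 1L]] <<- tibble::tibble(check = check, detail = detail)

  for (lib in names(b$filtered)) {
    if (!lib %in% names(b$raw)) {
      note("raw_missing", paste("filtered library", lib, "has no raw matrix"))
      next
    }
    extra <- setdiff(b$filtered[[lib]]$barcode_ids, b$raw[[lib]]$barcode_ids)
    if (length(extra))
      note("filtered_not_in_raw",
           paste0(lib, ": ", length(extra), " filtered barcodes absent from raw"))
  }
  unknown <- setdiff(b$library_donors$donor_id, b$donors$donor_id)
  if (length(unknown))
    note("unknown_donor", paste("library mapped to unknown donor:",
                                paste(unknown, collapse = ",")))
  orphan <- setdiff(names(b$raw), b$library_donors$library_id)
  if (length(orphan))
    note("library_without_donor", paste(orphan, collapse = ","))
  if (!is.null(b$cells)) {
    if (anyDuplicated(b$cells[c("library_id", "barcode_id")]))
      note("duplicate_cell_key", "duplicated (library_id, barcode_id)")
    if (any(b$cells$pMT < 0 | b$cells$pMT > 100, na.rm = TRUE))
      note("pmt_range", "pMT outside [0, 100]")
    if (any(b$cells$nFEA > b$cells$nUMI, na.rm = TRUE))
      note("nfea_gt_numi", "nFEA exceeds nUMI")
  }
  if (any(b$donors$hba1c <= 0)) note("hba1c_positive", "non-positive HbA1c")
  if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(check = character(), detail = character())
}
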