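# Readers and writers. Two dialects come in: raw measurement tables
# (Kd/Ki/pKd/pKi values or qualitative "not active" annotations, thresholded
# here), and pre-thresholded status tables. Two serializations go out: a
# triplet TSV and a dense status-matrix TSV ("1" active, "0" inactive, "."
# null). All output ordering follows the relation's reference-set order so
# repeated runs are byte-identical.

.unit_factor <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
                  nM = 1e-9, pM = 1e-12)
.quant_types <- c("Kd", "Ki", "pKd", "pKi")

.default_dialect <- function() {
  list(ligand = "ligand_id", target = "target_id", type = "type",
       value = "value", units = "units", qualifier = "qualifier")
}

#' Read a raw bioactivity measurement table
#'
#' Parses a TSV of per-measurement records. Each row is either quantitative
#' (a Kd/Ki value with molar-prefixed units, or a unitless pKd/pKi) or
#' qualitative (a "not active" annotation); carrying both is malformed.
#' Quantitative Kd/Ki values are normalized to molar.
#'
#' @param path TSV file with a header.
#' @param dialect Optional named list overriding the default column names
#'   (`ligand = "ligand_id"`, `target = "target_id"`, `type`, `value`,
#'   `units`, `qualifier`).
#' @param type_map Optional named character vector mapping additional
#'   measurement-type tokens onto supported ones (for example
#'   `c(IC50 = "Kd")`). Off by default: unmapped types are an error, since
#'   mixing assay read-outs under one threshold is a modelling decision the
#'   caller must opt into.
#' @return A data frame of records: `ligand`, `target`, `kind`
#'   (`"quantitative"`/`"qualitative"`), `measure_type`, `value` (molar for
#'   Kd/Ki, log10 units for pKd/pKi, `NA` for qualitative), `qualifier`.
#' @export
read_measurements <- function(path, dialect = NULL, type_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(.default_dialect(), as.list(dialect %||% list()))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  for (col in c(d$ligand, d$target, d$type, d$value)) {
    if (!col %in% names(raw)) {
      stop("missing column ", sQuote(col), " in ", path)
    }
  }
  qual_col <- if (d$qualifier %in% names(raw)) raw[[d$qualifier]] else
    rep("", nrow(raw))
  units_col <- if (d$units %in% names(raw)) raw[[d$units]] else
    rep("", nrow(raw))

  n <- nrow(raw)
  out <- data.frame(ligand = trimws(raw[[d$ligand]]),
                    target = trimws(raw[[d$target]]),
                    kind = character(n), measure_type = NA_character_,
                    value = NA_real_, qualifier = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    type <- trimws(raw[[d$type]][i])
    val <- trimws(raw[[d$value]][i])
    unit <- trimws(units_col[i])
    qual <- trimws(qual_col[i])
    has_qual <- nzchar(qual)
    has_quant <- nzchar(val) || nzchar(type)
    if (has_qual) {
      if (nzchar(val)) {
        stop("line ", line, ": record carries both a value and a qualifier")
      }
      if (!tolower(gsub("_", " ", qual)) %in% "not active") {
        stop("line ", line, ": unknown qualifier ", sQuote(qual))
      }
      out$kind[i] <- "qualitative"
      out$qualifier[i] <- "not_active"
      next
    }
    if (!has_quant) stop("line ", line, ": empty record")
    if (!is.null(type_map) && type %in% names(type_map)) {
      type <- type_map[[type]]
    }
    if (!type %in% .quant_types) {
      stop("line ", line, ": unsupported measurement type ", sQuote(type),
           " (supported: ", paste(.quant_types, collapse = ", "),
           "; map others explicitly via type_map)")
    }
    v <- suppressWarnings(as.numeric(val))
    if (is.na(v)) stop("line ", line, ": malformed value ", sQuote(val))
    if (type %in% c("Kd", "Ki")) {
      if (v <= 0) stop("line ", line, ": non-positive ", type, " value ", v)
      if (!unit %in% names(.unit_factor)) {
        stop("line ", line, ": unknown unit token ", sQuote(unit),
             " (supported: ", paste(names(.unit_factor), collapse = ", "),
             ")")
      }
      v <- v * .unit_factor[[unit]]
    }
    out$kind[i] <- "quantitative"
    out$measure_type[i] <- type
    out$value[i] <- v
  }
  out
}

#' Threshold measurement records into activity statuses
#'
#' Applies the activity threshold per record — a qualitative "not active"
#' annotation or a Kd/Ki strictly above `threshold` (default 3e-6 M) is
#' inactive, a Kd/Ki at or below it is active; pKd/pKi records compare
#' against `pk_threshold` (default 5.5, at-or-above is active) — and then
#' aggregates per (ligand, target) pair: records that all agree keep their
#' status, any disagreement between active and inactive becomes null
#' (conflicting annotations convey no reliable status).
#'
#' The boundary reads "larger than" strictly, so Kd exactly at the threshold
#' is active. 3 uM corresponds to pK 5.52; the nominal 5.5 is kept as its own
#' threshold for pK-typed records, so mixed-type records for one pair can in
#' edge cases disagree, which then resolves to null like any other conflict.
#'
#' @param records Data frame from [read_measurements()].
#' @param threshold Molar activity cutoff for Kd/Ki; must be positive.
#' @param pk_threshold Cutoff on the log10 scale for pKd/pKi.
#' @return Data frame of status triples (`ligand`, `target`, `status`), one
#'   row per pair, sorted by (ligand, target) so the output is independent of
#'   record order.
#' @export
threshold_records <- function(records, threshold = 3e-6, pk_threshold = 5.5) {
  stopifnot(is.data.frame(records), threshold > 0)
  status <- character(nrow(records))
  qual <- records$kind == "qualitative"
  status[qual] <- "inactive"
  pk <- records$measure_type %in% c("pKd", "pKi")
  quant <- records$kind == "quantitative"
  status[quant & !pk] <- ifelse(records$value[quant & !pk] > threshold,
                                "inactive", "active")
  status[quant & pk] <- ifelse(records$value[quant & pk] < pk_threshold,
                               "inactive", "active")
  key <- paste(records$ligand, records$target, sep = "\r")
  agg <- tapply(status, key, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else "null"
  })
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(ligand = vapply(parts, `[`, "", 1L),
                    target = vapply(parts, `[`, "", 2L),
                    status = as.character(agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$ligand, out$target, method = "radix"), , drop = FALSE] |>
    (\(x) {rownames(x) <- NULL; x})()
}

#' Read and write status-triple tables
#'
#' The triplet TSV has columns `ligand_id`, `target_id`, `status` with status
#' tokens among [lt_states()] (matched case-insensitively after trimming).
#' On write, null rows are omitted by default — [lt_relation()] restores
#' unmentioned pairs as null — but the full reference sets are then only
#' recoverable when passed explicitly, so `keep_null = TRUE` round-trips the
#' grid exactly.
#'
#' @param path TSV file.
#' @return `read_status_triples()`: a data frame (`ligand`, `target`,
#'   `status`) ready for [lt_relation()].
#' @export
read_status_triples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  need <- c("ligand_id", "target_id", "status")
  if (!all(need %in% names(raw))) {
    stop("triplet file must have columns ", paste(need, collapse = ", "))
  }
  status <- tolower(trimws(raw$status))
  bad <- which(!status %in% lt_states())
  if (length(bad)) {
    stop("line ", bad[1L] + 1L, ": unknown status token ",
         sQuote(raw$status[bad[1L]]))
  }
  data.frame(ligand = trimws(raw$ligand_id), target = trimws(raw$target_id),
             status = status, stringsAsFactors = FALSE)
}

#' @rdname read_status_triples
#' @param rel An [lt_relation()].
#' @param keep_null Also write the null pairs (default `FALSE`).
#' @export
write_status_triples <- function(rel, path, keep_null = FALSE) {
  stopifnot(inherits(rel, "lt_relation"))
  codes <- unclass(rel)
  idx <- which(if (keep_null) codes >= 1L else codes != 3L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(ligand_id = rownames(codes)[idx[, 1L]],
                    target_id = colnames(codes)[idx[, 2L]],
                    status = lt_states()[codes[idx]],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the dense status matrix
#'
#' A TSV grid with the target ids as header, one row per ligand (ligand id in
#' the first column), and cell tokens `"1"` (active), `"0"` (inactive), `"."`
#' (null). Round-trips a relation exactly, including its reference-set
#' order.
#'
#' @param rel An [lt_relation()].
#' @param path TSV file.
#' @export
write_status_matrix <- function(rel, path) {
  stopifnot(inherits(rel, "lt_relation"))
  codes <- unclass(rel)
  tok <- matrix(c("1", "0", ".")[codes], nrow = nrow(codes))
  df <- data.frame(ligand_id = rownames(codes), tok,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("ligand_id", colnames(codes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_status_matrix
#' @return `read_status_matrix()`: an [lt_relation()].
#' @export
read_status_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty status-matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(cells[[1L]])
  tgt <- header[-1L]
  ncol_expect <- length(header)
  codes <- matrix(3L, nrow = length(cells) - 1L, ncol = length(tgt))
  lig <- character(length(cells) - 1L)
  for (r in seq_along(cells)[-1L]) {
    row <- trimws(cells[[r]])
    if (length(row) != ncol_expect) {
      stop("row ", r, ": expected ", ncol_expect, " columns, found ",
           length(row))
    }
    lig[r - 1L] <- row[1L]
    code <- match(row[-1L], c("1", "0", "."))
    if (anyNA(code)) {
      bad <- which(is.na(code))[1L]
      stop("row ", r, ", column ", bad + 1L, ": unknown token ",
           sQuote(row[-1L][bad]))
    }
    codes[r - 1L, ] <- code
  }
  dimnames(codes) <- list(.check_ids(lig, "ligand"),
                          .check_ids(tgt, "target"))
  structure(codes, class = "lt_relation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
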