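# Data-completeness measures. Global data completeness (GDC) is the fraction
# of LT pairs with known (active or inactive) status; local data completeness
# restricts the same fraction to one ligand's row or one target's column.
# The mean of the per-ligand LDCs equals the GDC equals the mean of the
# per-target LDCs -- an algebraic identity that holds for every relation and
# is verified (to floating tolerance) by completeness().

#' Global data completeness
#'
#' Fraction of all ligand-target pairs whose activity status is known
#' (active or inactive, as opposed to null).
#'
#' @param rel An [lt_relation()] with a non-empty grid.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' gdc(toy_example_relation())  # 6 known pairs of 10
gdc <- function(rel) {
  stopifnot(inherits(rel, "lt_relation"))
  if (prod(dim(rel)) == 0) stop("empty relation: GDC is undefined")
  cc <- state_counts(rel)
  (cc[["active"]] + cc[["inactive"]]) / prod(dim(rel))
}

#' Local data completeness
#'
#' Per-ligand (row-wise) or per-target (column-wise) fraction of known pairs.
#' With `id = NULL` the full named vector over the reference set is returned.
#'
#' @param rel An [lt_relation()].
#' @param id Optional single identifier; unknown ids are an error.
#' @return Named numeric vector (or a single number when `id` is given).
#' @export
ldc_ligand <- function(rel, id = NULL) {
  stopifnot(inherits(rel, "lt_relation"))
  if (ncol(rel) == 0) stop("no targets: ligand LDC is undefined")
  v <- rowSums(unclass(rel) != 3L) / ncol(rel)
  if (is.null(id)) return(v)
  if (!id %in% rownames(rel)) stop("unknown ligand id: ", sQuote(id),
                                   call. = FALSE)
  v[[id]]
}

#' @rdname ldc_ligand
#' @export
ldc_target <- function(rel, id = NULL) {
  stopifnot(inherits(rel, "lt_relation"))
  if (nrow(rel) == 0) stop("no ligands: target LDC is undefined")
  v <- colSums(unclass(rel) != 3L) / nrow(rel)
  if (is.null(id)) return(v)
  if (!id %in% colnames(rel)) stop("unknown target id: ", sQuote(id),
                                   call. = FALSE)
  v[[id]]
}

.step_cdf <- function(x) {
  x <- sort(x)
  ux <- unique(x)
  data.frame(value = ux,
             cum_fraction = cumsum(tabulate(match(x, ux))) / length(x))
}

#' Completeness report for a relation
#'
#' Computes the GDC, the per-ligand and per-target LDC vectors, their
#' mean/median summaries, and the exact empirical step CDFs of both LDC
#' distributions (no binning). The report verifies the identity
#' mean-ligand-LDC = GDC = mean-target-LDC to `tol`.
#'
#' @param rel An [lt_relation()] with a non-empty grid.
#' @param tol Relative tolerance for the mean-LDC identity check.
#' @return An object of class `lt_completeness` with fields `gdc`,
#'   `ldc_ligand`, `ldc_target`, `ligand_cdf`, `target_cdf`,
#'   `mean_ldc_ligand`, `mean_ldc_target`, `median_ldc_ligand`,
#'   `median_ldc_target`, and per-id count tables `ligand_table`,
#'   `target_table` (columns id, n_active, n_inactive, n_null, ldc).
#' @export
#' @examples
#' completeness(toy_example_relation())
completeness <- function(rel, tol = 1e-12) {
  stopifnot(inherits(rel, "lt_relation"))
  g <- gdc(rel)
  ldl <- ldc_ligand(rel)
  ldt <- ldc_target(rel)
  for (m in c(mean(ldl), mean(ldt))) {
    if (abs(m - g) > tol * max(1, abs(g))) {
      stop("internal error: mean LDC differs from GDC beyond tolerance")
    }
  }
  codes <- unclass(rel)
  ligand_table <- data.frame(
    id = rownames(rel),
    n_active = rowSums(codes == 1L),
    n_inactive = rowSums(codes == 2L),
    n_null = rowSums(codes == 3L),
    ldc = ldl,
    row.names = NULL, stringsAsFactors = FALSE)
  target_table <- data.frame(
    id = colnames(rel),
    n_active = colSums(codes == 1L),
    n_inactive = colSums(codes == 2L),
    n_null = colSums(codes == 3L),
    ldc = ldt,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    gdc = g,
    ldc_ligand = ldl, ldc_target = ldt,
    ligand_cdf = .step_cdf(ldl), target_cdf = .step_cdf(ldt),
    mean_ldc_ligand = mean(ldl), mean_ldc_target = mean(ldt),
    median_ldc_ligand = stats::median(ldl),
    median_ldc_target = stats::median(ldt),
    ligand_table = ligand_table, target_table = target_table,
    n_ligands = nrow(rel), n_targets = ncol(rel)),
    class = "lt_completeness")
}

#' @export
print.lt_completeness <- function(x, ...) {
  cat("Data completeness (", x$n_ligands, " ligands x ", x$n_targets,
      " targets)\n", sep = "")
  cat("  GDC: ", formatC(x$gdc, digits = 4, format = "f"), "\n", sep = "")
  cat("  ligand LDC: mean ", formatC(x$mean_ldc_ligand, digits = 4,
      format = "f"), ", median ", formatC(x$median_ldc_ligand, digits = 4,
      format = "f"), "\n", sep = "")
  cat("  target LDC: mean ", formatC(x$mean_ldc_target, digits = 4,
      format = "f"), ", median ", formatC(x$median_ldc_target, digits = 4,
      format = "f"), "\n", sep = "")
  invisible(x)
}

#' @export
plot.lt_completeness <- function(x, which = c("ligand", "target"), ...) {
  which <- match.arg(which)
  cdf <- if (which == "ligand") x$ligand_cdf else x$target_cdf
  plot(stats::stepfun(cdf$value, c(0, cdf$cum_fraction)),
       xlim = c(0, 1), xlab = paste0(which, " local data completeness"),
       ylab = "cumulative fraction", do.points = FALSE,
       main = paste("Cumulative distribution of", which, "LDC"), ...)
  graphics::abline(v = x$gdc, lty = 2, col = "grey40")
  invisible(x)
}

#' Write a completeness report to disk
#'
#' Emits one TSV per axis (columns `id`, `n_active`, `n_inactive`, `n_null`,
#' `ldc`) plus a JSON summary block with the GDC and the LDC mean/median
#' summaries.
#'
#' @param report An [completeness()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_completeness <- function(report, dir) {
  stopifnot(inherits(report, "lt_completeness"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ligand = file.path(dir, "ldc_ligand.tsv"),
             target = file.path(dir, "ldc_target.tsv"),
             summary = file.path(dir, "completeness.json"))
  utils::write.table(report$ligand_table, paths[["ligand"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$target_table, paths[["target"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_ligands = report$n_ligands, n_targets = report$n_targets,
         gdc = report$gdc,
         mean_ldc_ligand = report$mean_ldc_ligand,
         median_ldc_ligand = report$median_ldc_ligand,
         mean_ldc_target = report$mean_ldc_target,
         median_ldc_target = report$median_ldc_target),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Validate an external dataset summary table
#'
#' Checks the internal consistency of published summary counts for an LT
#' dataset: the class counts must sum to the printed total, and the printed
#' total must equal `n_ligands * n_targets` for a total (partitioned)
#' relation. Published tables sometimes fail these checks; the validator
#' reports every discrepancy rather than silently reconciling them.
#'
#' @param n_ligands,n_targets Grid dimensions.
#' @param active,inactive Known-pair class counts.
#' @param null Optional null-pair count.
#' @param total Optional printed total pair count.
#' @return An object of class `lt_summary_check` with logical `consistent`
#'   and a character vector `problems` (empty when consistent).
#' @export
#' @examples
#' # a published kinase-panel summary whose class counts oversum the total
#' validate_summary_counts(250, 433, active = 4729, inactive = 69419,
#'                         null = 34104, total = 108250)
validate_summary_counts <- function(n_ligands, n_targets, active, inactive,
                                    null = NULL, total = NULL) {
  grid <- n_ligands * n_targets
  problems <- character()
  add <- function(p, msg) if (p) c(problems, msg) else problems
  if (is.null(total)) total <- grid
  problems <- add(total != grid,
                  sprintf("printed total (%s) differs from n*m grid size (%s)",
                          format(total, big.mark = ","),
                          format(grid, big.mark = ",")))
  if (!is.null(null)) {
    s <- active + inactive + null
    problems <- add(s != total,
                    sprintf("class counts sum to %s, not the printed total %s",
                            format(s, big.mark = ","),
                            format(total, big.mark = ",")))
    problems <- add(s != grid && total == grid,
                    sprintf("class counts sum to %s, not the grid size %s",
                            format(s, big.mark = ","),
                            format(grid, big.mark = ",")))
  }
  problems <- add(active + inactive > grid,
                  "known-pair counts exceed the grid size")
  structure(list(consistent = length(unique(problems)) == 0,
                 problems = unique(problems),
                 gdc = (active + inactive) / grid),
            class = "lt_summary_check")
}

#' @export
print.lt_summary_check <- function(x, ...) {
  if (x$consistent) {
    cat("Summary table is internally consistent. GDC =",
        formatC(x$gdc, digits = 4, format = "f"), "\n")
  } else {
    cat("Summary table is INCONSISTENT:\n")
    for (p in x$problems) cat("  - ", p, "\n", sep = "")
    cat("GDC from known counts over the n*m grid =",
        formatC(x$gdc, digits = 4, format = "f"), "\n")
  }
  invisible(x)
}
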