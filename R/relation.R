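# Ternary ligand-target relations: every (ligand, target) pair carries exactly
# one of three activity states. The relation is stored as an integer code
# matrix (1 = active, 2 = inactive, 3 = null) with ligand ids as row names and
# target ids as column names; the three binary subrelations are recovered by
# state-equality masking, which is provably equivalent to materializing the
# three-dimensional reference set.

#' The three activity states
#'
#' Every ligand-target (LT) pair is in exactly one of three states:
#' `"active"`, `"inactive"`, or `"null"`. The null state means the pair has
#' never been measured (experimentally or computationally); it is distinct
#' from inactive, which records a measured lack of activity.
#'
#' @return Character vector of the three state names, in canonical order.
#' @export
#' @examples
#' lt_states()
lt_states <- function() c("active", "inactive", "null")

.state_code <- function(status) {
  code <- match(status, lt_states())
  if (anyNA(code)) {
    bad <- unique(status[is.na(code)])
    stop("unknown activity status token(s): ",
         paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(lt_states(), collapse = ", "),
         call. = FALSE)
  }
  code
}

.check_ids <- function(ids, what) {
  ids <- trimws(as.character(ids))
  if (any(!nzchar(ids))) stop("empty ", what, " identifier", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate ", what, " identifiers in reference set: ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  }
  ids
}

#' Build a ternary ligand-target relation
#'
#' Constructs the total assignment of every pair of the ligand x target grid
#' to one of the three activity states. Pairs not mentioned in `triples` are
#' null by definition: absence of data *is* the null state.
#'
#' @param triples A data frame with columns `ligand`, `target`, `status`
#'   (values among [lt_states()]), one row per known pair. May be `NULL` or
#'   zero-row, in which case explicit reference sets are required for a
#'   non-empty grid.
#' @param ligands,targets Optional explicit reference sets (character). When
#'   given, every id in `triples` must belong to them and the row/column order
#'   of the relation follows them; otherwise the reference sets are the unique
#'   ids of `triples` in first-appearance order.
#' @return An object of class `lt_relation`: an integer code matrix
#'   (1 active, 2 inactive, 3 null) with ligand row names and target column
#'   names.
#' @details A duplicated `(ligand, target)` pair is an error naming the pair;
#'   resolving conflicting measurements is the job of [threshold_records()],
#'   which maps disagreement to null before the relation is built.
#' @seealso [ligand_profile()], [state_counts()], [gdc()], [polypharm()]
#' @export
#' @examples
#' rel <- lt_relation(
#'   data.frame(ligand = c("l1", "l1", "l1", "l2", "l2", "l2"),
#'              target = c("t1", "t2", "t3", "t2", "t4", "t5"),
#'              status = c("active", "active", "inactive",
#'                         "active", "active", "inactive")),
#'   targets = c("t1", "t2", "t3", "t4", "t5"))
#' rel
#' state_counts(rel)
lt_relation <- function(triples = NULL, ligands = NULL, targets = NULL) {
  if (is.null(triples)) {
    triples <- data.frame(ligand = character(), target = character(),
                          status = character(), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(triples)) stop("'triples' must be a data frame")
  need <- c("ligand", "target", "status")
  if (!all(need %in% names(triples))) {
    stop("'triples' must have columns ", paste(need, collapse = ", "))
  }
  lig <- trimws(as.character(triples$ligand))
  tgt <- trimws(as.character(triples$target))
  code <- .state_code(as.character(triples$status))

  if (is.null(ligands)) ligands <- unique(lig) else {
    ligands <- .check_ids(ligands, "ligand")
    unknown <- setdiff(lig, ligands)
    if (length(unknown)) {
      stop("ligand id(s) outside the explicit reference set: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(targets)) targets <- unique(tgt) else {
    targets <- .check_ids(targets, "target")
    unknown <- setdiff(tgt, targets)
    if (length(unknown)) {
      stop("target id(s) outside the explicit reference set: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
  }
  ligands <- .check_ids(ligands, "ligand")
  targets <- .check_ids(targets, "target")

  key <- paste(lig, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1L]
    stop("duplicate (ligand, target) pair in input: (",
         lig[first], ", ", tgt[first],
         "); resolve conflicting records upstream (see threshold_records)",
         call. = FALSE)
  }

  m <- matrix(3L, nrow = length(ligands), ncol = length(targets),
              dimnames = list(ligands, targets))
  if (length(lig)) {
    m[cbind(match(lig, ligands), match(tgt, targets))] <- code
  }
  structure(m, class = "lt_relation")
}

#' @export
print.lt_relation <- function(x, ...) {
  cc <- state_counts(x)
  cat("Ternary ligand-target relation: ", nrow(x), " ligands x ",
      ncol(x), " targets\n", sep = "")
  cat("  active: ", cc[["active"]], "  inactive: ", cc[["inactive"]],
      "  null: ", cc[["null"]], "\n", sep = "")
  if (prod(dim(x)) > 0) {
    cat("  global data completeness: ",
        formatC(gdc(x), digits = 4, format = "f"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.lt_relation <- function(object, ...) {
  print(object)
  if (prod(dim(object)) > 0) {
    ldl <- ldc_ligand(object)
    ldt <- ldc_target(object)
    cat("  ligand LDC: median ", formatC(stats::median(ldl), digits = 3,
        format = "f"), ", mean ", formatC(mean(ldl), digits = 3,
        format = "f"), "\n", sep = "")
    cat("  target LDC: median ", formatC(stats::median(ldt), digits = 3,
        format = "f"), ", mean ", formatC(mean(ldt), digits = 3,
        format = "f"), "\n", sep = "")
  }
  invisible(object)
}

#' Reference sets of a relation
#'
#' @param rel An [lt_relation()].
#' @return Character vector of ligand (row) or target (column) identifiers.
#' @export
ligands <- function(rel) {
  stopifnot(inherits(rel, "lt_relation"))
  rownames(rel)
}

#' @rdname ligands
#' @export
targets <- function(rel) {
  stopifnot(inherits(rel, "lt_relation"))
  colnames(rel)
}

#' Class cardinalities of a ternary relation
#'
#' Counts of active, inactive, and null LT pairs. Because the three states
#' partition the grid, the counts always sum to `n * m`.
#'
#' @param rel An [lt_relation()].
#' @return Named integer vector `c(active=, inactive=, null=)`.
#' @export
state_counts <- function(rel) {
  stopifnot(inherits(rel, "lt_relation"))
  codes <- unclass(rel)
  c(active = sum(codes == 1L), inactive = sum(codes == 2L),
    null = sum(codes == 3L))
}

#' Project a ternary relation onto a binary incidence matrix
#'
#' The projection of the subrelation of one activity state onto the
#' ligand x target grid: a 0/1 indicator that is 1 exactly where the pair
#' carries `state`. Summed over the three states, the indicators are the
#' all-ones matrix (the subrelations partition the grid), so the projections
#' jointly carry the full information of the ternary relation.
#'
#' @param rel An [lt_relation()].
#' @param state One of [lt_states()].
#' @return Integer 0/1 matrix with the relation's dimnames and attribute
#'   `state`.
#' @export
state_incidence <- function(rel, state) {
  stopifnot(inherits(rel, "lt_relation"))
  state <- match.arg(state, lt_states())
  inc <- (unclass(rel) == match(state, lt_states())) + 0L
  attr(inc, "state") <- state
  inc
}

#' Rebuild a relation from its three binary incidences
#'
#' Inverse of [state_incidence()]: given the active/inactive/null indicator
#' matrices (which must partition the grid cell-wise), reconstitutes the
#' ternary relation. The round trip through the three projections is the
#' identity.
#'
#' @param active,inactive,null 0/1 matrices of identical dimension and
#'   dimnames. `null` may be omitted and is then inferred as the complement.
#' @return An [lt_relation()].
#' @export
lt_relation_from_incidence <- function(active, inactive, null = NULL) {
  if (is.null(null)) null <- 1L - active - inactive
  if (!identical(dim(active), dim(inactive)) ||
      !identical(dim(active), dim(null))) {
    stop("incidence matrices must share one dimension")
  }
  tot <- active + inactive + null
  if (any(tot != 1L) || any(active < 0) || any(inactive < 0) || any(null < 0)) {
    stop("incidence matrices must partition the grid: ",
         "cell-wise sum of the three indicators must be exactly 1")
  }
  codes <- 1L * (active == 1L) + 2L * (inactive == 1L) + 3L * (null == 1L)
  codes <- matrix(as.integer(codes), nrow = nrow(active),
                  dimnames = dimnames(active))
  structure(codes, class = "lt_relation")
}

# ---- subsets of a reference set -------------------------------------------

#' Subset of a reference set
#'
#' A small value class for subsets of the target (or ligand) reference set,
#' carrying the reference set along so that set algebra can refuse to combine
#' subsets drawn from different universes.
#'
#' @param members Character vector of member ids (subset of `reference`).
#' @param reference Character vector, the full reference set.
#' @return An object of class `lt_set`.
#' @export
lt_set <- function(members, reference) {
  members <- as.character(members)
  reference <- as.character(reference)
  if (!all(members %in% reference)) {
    stop("members outside the reference set: ",
         paste(sQuote(setdiff(members, reference)), collapse = ", "))
  }
  # keep reference order, drop duplicates
  structure(list(members = reference[sort(unique(match(members, reference)))],
                 reference = reference),
            class = "lt_set")
}

#' @export
print.lt_set <- function(x, ...) {
  cat("{", paste(x$members, collapse = ", "), "} of ",
      length(x$reference), "-element reference set\n", sep = "")
  invisible(x)
}

#' @export
length.lt_set <- function(x) length(x$members)

.same_reference <- function(a, b) {
  if (!inherits(a, "lt_set") || !inherits(b, "lt_set")) {
    stop("set operations need lt_set operands")
  }
  if (!identical(a$reference, b$reference)) {
    stop("mismatched reference sets: set operations are only defined ",
         "within one reference set")
  }
}

#' Set algebra on reference-set subsets
#'
#' Intersection and union of two subsets of one reference set, implemented as
#' the element-wise min (intersection) and max (union) of their characteristic
#' 0/1 vectors over the reference set — the ternary-relation form of the
#' classical set operations.
#'
#' @param a,b [lt_set()] objects over the same reference set.
#' @return An [lt_set()].
#' @export
profile_intersection <- function(a, b) {
  .same_reference(a, b)
  ca <- as.integer(a$reference %in% a$members)
  cb <- as.integer(b$reference %in% b$members)
  lt_set(a$reference[pmin(ca, cb) == 1L], a$reference)
}

#' @rdname profile_intersection
#' @export
profile_union <- function(a, b) {
  .same_reference(a, b)
  ca <- as.integer(a$reference %in% a$members)
  cb <- as.integer(b$reference %in% b$members)
  lt_set(a$reference[pmax(ca, cb) == 1L], a$reference)
}

# ---- unary profiles -------------------------------------------------------

.profile <- function(id, axis, states, reference) {
  structure(list(id = id, axis = axis,
                 active = lt_set(reference[states == 1L], reference),
                 inactive = lt_set(reference[states == 2L], reference),
                 null = lt_set(reference[states == 3L], reference)),
            class = "lt_profile")
}

#' Ligand and target activity profiles
#'
#' The projection of one ligand's row (or one target's column) of the ternary
#' relation down to the opposite reference set: three disjoint subsets — the
#' targets the ligand is active, inactive, and null against (or the ligands a
#' target is active/inactive/null against) — that together partition that
#' reference set.
#'
#' @param rel An [lt_relation()].
#' @param ligand,target Identifier present in the relation's reference set.
#' @return An object of class `lt_profile` with fields `id`, `axis`
#'   (`"ligand"` or `"target"`), and [lt_set()]s `active`, `inactive`, `null`.
#' @export
#' @examples
#' rel <- toy_example_relation()
#' ligand_profile(rel, "l1")
ligand_profile <- function(rel, ligand) {
  stopifnot(inherits(rel, "lt_relation"))
  i <- match(ligand, rownames(rel))
  if (is.na(i)) stop("unknown ligand id: ", sQuote(ligand), call. = FALSE)
  .profile(ligand, "ligand", unclass(rel)[i, ], colnames(rel))
}

#' @rdname ligand_profile
#' @export
target_profile <- function(rel, target) {
  stopifnot(inherits(rel, "lt_relation"))
  j <- match(target, colnames(rel))
  if (is.na(j)) stop("unknown target id: ", sQuote(target), call. = FALSE)
  .profile(target, "target", unclass(rel)[, j], rownames(rel))
}

#' @export
print.lt_profile <- function(x, ...) {
  opp <- if (x$axis == "ligand") "targets" else "ligands"
  cat("Activity profile of ", x$axis, " ", sQuote(x$id), " over ",
      length(x$active$reference), " ", opp, "\n", sep = "")
  cat("  active  (", length(x$active), "): ",
      paste(x$active$members, collapse = ", "), "\n", sep = "")
  cat("  inactive(", length(x$inactive), "): ",
      paste(x$inactive$members, collapse = ", "), "\n", sep = "")
  cat("  null    (", length(x$null), ")\n", sep = "")
  invisible(x)
}

#' Activity-state fractions of a profile
#'
#' The fractions of the opposite reference set that are active, inactive, and
#' null for one ligand (or target). The three fractions sum to 1.
#'
#' @param profile An `lt_profile` from [ligand_profile()] or
#'   [target_profile()].
#' @return Named numeric vector `c(active=, inactive=, null=)`.
#' @export
activity_fractions <- function(profile) {
  stopifnot(inherits(profile, "lt_profile"))
  m <- length(profile$active$reference)
  if (m == 0) stop("empty reference set: fractions are undefined")
  c(active = length(profile$active) / m,
    inactive = length(profile$inactive) / m,
    null = length(profile$null) / m)
}

#' Two-ligand, five-target worked example
#'
#' The small hand-enumerable dataset used throughout the documentation and
#' tests: ligand `l1` is active on `t1`, `t2` and inactive on `t3`; ligand
#' `l2` is active on `t2`, `t4` and inactive on `t5`; the remaining four
#' pairs are null.
#'
#' @return An [lt_relation()] with class cardinalities (4, 2, 4).
#' @export
toy_example_relation <- function() {
  lt_relation(
    data.frame(ligand = c("l1", "l1", "l1", "l2", "l2", "l2"),
               target = c("t1", "t2", "t3", "t2", "t4", "t5"),
               status = c("active", "active", "inactive",
                          "active", "active", "inactive"),
               stringsAsFactors = FALSE),
    ligands = c("l1", "l2"),
    targets = c("t1", "t2", "t3", "t4", "t5"))
}
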