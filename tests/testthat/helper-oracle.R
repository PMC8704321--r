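# Naive reference implementation used as an independent oracle: the relation
# is held as an explicit data frame of (ligand, target, state) triples over
# the full three-dimensional reference set, and every quantity is computed by
# plain enumeration and subsetting. Deliberately slow and simple.

random_relation <- function(n, m, probs = c(0.2, 0.4, 0.4)) {
  lig <- sprintf("l%02d", seq_len(n))
  tgt <- sprintf("t%02d", seq_len(m))
  codes <- matrix(sample.int(3L, n * m, replace = TRUE, prob = probs),
                  n, m, dimnames = list(lig, tgt))
  structure(codes, class = "lt_relation")
}

# explicit triple table: one row per (l, t) with its state name
oracle_triples <- function(rel) {
  codes <- unclass(rel)
  expand <- expand.grid(ligand = rownames(codes), target = colnames(codes),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand$state <- lt_states()[codes[cbind(match(expand$ligand, rownames(codes)),
                                          match(expand$target, colnames(codes)))]]
  expand
}

oracle_counts <- function(tr) {
  vapply(lt_states(), function(s) sum(tr$state == s), integer(1))
}

oracle_profile_sets <- function(tr, id, axis = "ligand") {
  rows <- tr[tr[[axis]] == id, ]
  opp <- if (axis == "ligand") "target" else "ligand"
  lapply(stats::setNames(lt_states(), lt_states()),
         function(s) sort(rows[[opp]][rows$state == s]))
}

oracle_gdc <- function(tr) mean(tr$state != "null")

oracle_pmin <- function(tr, id) {
  sum(tr$ligand == id & tr$state == "active")
}

oracle_pmax <- function(tr, id) {
  sum(tr$ligand == id & tr$state %in% c("active", "null"))
}

oracle_p_hat <- function(tr, id) {
  rows <- tr[tr$ligand == id & tr$state != "null", ]
  if (nrow(rows) == 0) NA_real_ else mean(rows$state == "active")
}

oracle_joint_counts <- function(tr, id1, id2) {
  s1 <- tr[tr$ligand == id1, ]
  s2 <- tr[tr$ligand == id2, ]
  s2 <- s2[match(s1$target, s2$target), ]
  counts <- matrix(0L, 3, 3, dimnames = list(lt_states(), lt_states()))
  for (a in lt_states()) for (b in lt_states()) {
    counts[a, b] <- sum(s1$state == a & s2$state == b)
  }
  counts
}

toy_triples <- function() {
  data.frame(ligand = c("l1", "l1", "l1", "l2", "l2", "l2"),
             target = c("t1", "t2", "t3", "t2", "t4", "t5"),
             status = c("active", "active", "inactive",
                        "active", "active", "inactive"),
             stringsAsFactors = FALSE)
}
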