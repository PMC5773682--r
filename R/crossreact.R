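#' Food cross-reactivity proportion matrix
#'
#' For every ordered food pair (x, y), the proportion of subjects reporting
#' a reaction to x who also report a reaction to y:
#' `M[x, y] = count(react x AND react y) / count(react x)`. The matrix is
#' asymmetric by construction; the diagonal is 1 wherever a food has any
#' reporters, and a food with zero reporters gets a missing (NA) row rather
#' than propagating NaN.
#'
#' @param pheno an [build_phenotypes()] result (its `case` matrix supplies
#'   the per-food reactor flags).
#' @return Object of class `fa_crossreact`: list with `proportion` (the
#'   matrix M), `counts` (the pairwise reactor-overlap counts) and
#'   `n_reactors` (per-food reactor counts).
#' @export
cross_react <- function(pheno) {
  stopifnot(inherits(pheno, "fa_pheno"))
  x <- pheno$case + 0
  counts <- t(x) %*% x
  n_react <- diag(counts)
  m <- counts / n_react            # rows scaled by the row food's reactors
  m[n_react == 0, ] <- NA_real_
  structure(
    list(proportion = m, counts = counts, n_reactors = n_react),
    class = "fa_crossreact"
  )
}

#' @export
print.fa_crossreact <- function(x, ...) {
  cat(sprintf("<fa_crossreact> %d foods; reactors per food: %d-%d\n",
              nrow(x$proportion), min(x$n_reactors), max(x$n_reactors)))
  invisible(x)
}

#' Food ordering for a cross-reactivity heatmap
#'
#' Orders foods by average-linkage hierarchical clustering on the
#' symmetrized similarity `max(M, t(M))` (distance `1 - similarity`), so
#' that mutually cross-reactive food groups appear adjacent. Foods with
#' missing rows are placed last, alphabetically. Tie distances are resolved
#' deterministically by ordering the distance computation over the label
#' sort order.
#'
#' @param cr an `fa_crossreact` object (or a proportion matrix).
#' @return Character vector of food labels in display order.
#' @export
order_for_heatmap <- function(cr) {
  m <- if (inherits(cr, "fa_crossreact")) cr$proportion else as.matrix(cr)
  labs <- sort(rownames(m))
  m <- m[labs, labs]
  usable <- !apply(is.na(m), 1, all)
  out_last <- labs[!usable]
  m <- m[usable, usable, drop = FALSE]
  if (nrow(m) < 2) return(c(rownames(m), out_last))
  s <- pmax(m, t(m))
  s[is.na(s)] <- 0
  d <- stats::as.dist(1 - s)
  hc <- stats::hclust(d, method = "average")
  c(rownames(m)[hc$order], out_last)
}
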