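# Hypergeometric over/under-representation of GA classes and dynamic modes
# across filtration steps: the frequency of a class among the lncRNAs retained
# by a step is contrasted with its frequency among the lncRNAs removed.

#' Hypergeometric tail probability
#'
#' For X ~ Hypergeometric(N, K, n) (n draws without replacement from N items
#' of which K are marked): the over-representation tail P(X >= k) or the
#' under-representation tail P(X <= k).
#'
#' @param k observed marked count among the draws.
#' @param K marked items in the population.
#' @param n draws.
#' @param N population size.
#' @param direction "over" or "under".
#' @return tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  stopifnot(all(k >= 0), all(K >= 0), all(n >= 0), all(K <= N), all(n <= N),
            all(k <= pmin(K, n)))
  if (direction == "over") phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else phyper(k, K, N - K, n)
}

#' Fold enrichment of a class across a filtration step
#'
#' FE = (k/n) / ((K-k)/(N-n)): the class frequency among retained lncRNAs
#' over its frequency among removed lncRNAs. When the removed set contains no
#' member of the class (K = k) the ratio is undefined and `Inf` is returned.
#'
#' @inheritParams hypergeom_tail
#' @return fold enrichment (>= 0, possibly `Inf`).
#' @export
fold_enrichment <- function(k, K, n, N) {
  stopifnot(n > 0, N > n)
  if (K - k == 0) return(Inf)
  (k / n) / ((K - k) / (N - n))
}

#' Bonferroni correction
#' @param p vector of p-values in (0, 1].
#' @param m number of tests (defaults to `length(p)`).
#' @return adjusted p-values, min(1, m * p).
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p > 0), all(p <= 1))
  p.adjust(p, method = "bonferroni", n = m)
}

resolve_labels <- function(cascade, labels) {
  mm <- cascade$membership
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% c("superclass", "ga_class", "mode")) {
    if (!labels %in% names(mm))
      stop("cascade has no '", labels, "' labelling")
    setNames(mm[[labels]], mm$gene_id)
  } else if (!is.null(names(labels))) {
    labels
  } else stop("labels must name a cascade labelling or be a named vector")
}

#' Class frequency-shift tests across one filtration step
#'
#' For the given step, the retained set is the step's membership and the
#' removed set is the previous step's membership minus it. Each label (or, in
#' the class-vs-class tabulation, each ordered label pair restricted to
#' members of the two classes) is tested with both hypergeometric tails; the
#' smaller tail is reported with its direction, together with the fold
#' enrichment and a Bonferroni adjustment over the batch.
#'
#' @param cascade a `cascade_result`.
#' @param step one of the step names after the first (see
#'   `cascade_step_names()`).
#' @param labels "superclass", "ga_class" or "mode" (a labelling stored in the
#'   cascade membership), or a named character vector mapping gene ids to
#'   labels.
#' @param tabulation "class_vs_rest" or "class_vs_class".
#' @return data.frame of class `enrichment_result` with columns step, label,
#'   other_label, tabulation, k, K, n, N, direction, p_value,
#'   fold_enrichment, p_adjusted, n_tests.
#' @export
class_shift_tests <- function(cascade, step, labels = "superclass",
                              tabulation = c("class_vs_rest", "class_vs_class")) {
  tabulation <- match.arg(tabulation)
  steps <- names(cascade$steps)
  i <- match(step, steps)
  if (is.na(i) || i == 1L)
    stop("step must be one of: ", paste(steps[-1L], collapse = ", "))
  lab <- resolve_labels(cascade, labels)
  prev <- intersect(cascade$steps[[i - 1L]], names(lab)[!is.na(lab)])
  ret <- intersect(cascade$steps[[i]], prev)
  rem <- setdiff(prev, ret)
  if (length(ret) == 0L || length(rem) == 0L)
    stop("degenerate step: empty retained or removed set at '", step, "'")

  lev <- sort(unique(lab[prev]))
  one_test <- function(label, other = NA_character_) {
    if (is.na(other)) {
      pop <- prev
      marked <- pop[lab[pop] == label]
    } else {
      pop <- prev[lab[prev] %in% c(label, other)]
      marked <- pop[lab[pop] == label]
    }
    N <- length(pop); K <- length(marked)
    drawn <- intersect(pop, ret)
    n <- length(drawn); k <- sum(lab[drawn] == label)
    if (n == 0L || n == N) return(NULL)  # degenerate sub-universe
    p_over <- hypergeom_tail(k, K, n, N, "over")
    p_under <- hypergeom_tail(k, K, n, N, "under")
    data.frame(step = step, label = label, other_label = other,
               tabulation = tabulation, k = k, K = K, n = n, N = N,
               direction = if (p_over <= p_under) "over" else "under",
               p_value = min(p_over, p_under),
               fold_enrichment = fold_enrichment(k, K, n, N),
               stringsAsFactors = FALSE)
  }

  rows <- if (tabulation == "class_vs_rest") {
    lapply(lev, one_test)
  } else {
    if (length(lev) < 2L) stop("class_vs_class requires >= 2 labels")
    pairs <- expand.grid(a = lev, b = lev, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    Map(one_test, pairs$a, pairs$b)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- do.call(rbind, rows)
  out$n_tests <- nrow(out)
  out$p_adjusted <- bonferroni(out$p_value, m = nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Write enrichment results as TSV
#' @param result an `enrichment_result` (or rbind of several).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
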