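# Temporal dynamic-mode templates over the 4-point timecourse and assignment
# of timecourses to modes by Pearson correlation. Templates are indexed by
# timepoint rank, not by hours, so the unevenly spaced sampling (0/6/24/120 h)
# does not reweight late intervals.

rate_sign_order <- function() {
  list(c("+", "+", "+"), c("+", "+", "-"), c("+", "-", "-"), c("+", "-", "+"),
       c("-", "+", "+"), c("-", "+", "-"), c("-", "-", "+"), c("-", "-", "-"))
}

rate_mode_names <- function() {
  c("permanently_activated_by_6h", "repressed_by_120h",
    "transiently_activated_at_6h", "transient_6h_spike_late_recovery",
    "activated_by_24h", "transiently_activated_at_24h",
    "activated_by_120h", "permanently_repressed_by_6h")
}

magnitude_signatures <- function() {
  list(c(0, 1, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1), c(0, 1, 1, 0),
       c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0), c(1, 0, 0, 1))
}

magnitude_mode_names <- function() {
  c("increased_by_6h", "increased_by_24h", "increased_by_120h",
    "transiently_increased_6_24h",
    "decreased_by_6h", "decreased_by_24h", "decreased_by_120h",
    "transiently_decreased_6_24h")
}

#' Enumerate the dynamic-mode templates of one family
#'
#' The "rate" family comprises all eight sign triples of expression change
#' between consecutive timepoints; each template is the cumulative sign path
#' anchored at 0 (e.g. signs (+,+,-) give template (0,1,2,1)). The
#' "magnitude" family comprises eight low/high (0/1) patterns over the four
#' timepoints: the four up-steps/pulse patterns and their complements
#' (constant patterns are excluded: Pearson correlation against a constant is
#' undefined).
#'
#' @param family "rate" or "magnitude".
#' @return data.frame with columns `family`, `name`, `signature`
#'   (list-column) and `template` (list-column of numeric 4-vectors), in a
#'   fixed, documented order.
#' @export
enumerate_modes <- function(family = c("rate", "magnitude")) {
  family <- match.arg(family)
  if (family == "rate") {
    sig <- rate_sign_order()
    tpl <- lapply(sig, function(s) cumsum(c(0, ifelse(s == "+", 1, -1))))
    nm <- rate_mode_names()
  } else {
    sig <- magnitude_signatures()
    tpl <- sig
    nm <- magnitude_mode_names()
  }
  data.frame(family = family, name = nm,
             signature = I(sig), template = I(tpl),
             stringsAsFactors = FALSE)
}

#' Mode templates of one family as a matrix
#' @param family "rate" or "magnitude".
#' @return 8 x 4 numeric matrix, rownames = mode names.
#' @export
mode_templates <- function(family = c("rate", "magnitude")) {
  m <- enumerate_modes(family)
  out <- do.call(rbind, m$template)
  rownames(out) <- m$name
  out
}

#' Signs of expression-rate change between consecutive timepoints
#'
#' The per-timepoint median across replicates is differenced; only the sign
#' of each difference is kept (magnitudes are ignored). Zero differences map
#' to "-" so that the sign alphabet stays two-valued (configurable).
#'
#' @param tc replicate x timepoint matrix.
#' @param zero_sign sign assigned to a zero difference.
#' @return character vector of "+"/"-" of length (timepoints - 1).
#' @export
rate_signs <- function(tc, zero_sign = "-") {
  med <- apply(tc, 2L, median)
  d <- diff(med)
  ifelse(d > 0, "+", ifelse(d < 0, "-", zero_sign))
}

#' Assign a timecourse to its best-matching dynamic mode
#'
#' Pearson correlation of the collapsed profile against each of the eight
#' family templates; the highest correlation wins. Ties are broken by
#' enumeration order with the tie flag set. A constant profile is
#' unassignable (zero variance), not an error.
#'
#' @param x a replicate x timepoint matrix or a plain numeric profile.
#' @param family "rate" or "magnitude".
#' @param stat replicate-collapsing statistic when `x` is a matrix.
#' @return list with `family`, `mode`, `r`, `runner_up`, `runner_r`, `tie`,
#'   `unassignable`.
#' @export
assign_mode <- function(x, family = c("rate", "magnitude"),
                        stat = c("mean", "median")) {
  family <- match.arg(family)
  profile <- if (is.matrix(x)) profile_of(x, match.arg(stat)) else as.numeric(x)
  tpl <- mode_templates(family)
  if (ncol(tpl) != length(profile))
    stop("profile length ", length(profile), " does not match templates")
  if (sd(profile) == 0)
    return(list(family = family, mode = NA_character_, r = NA_real_,
                runner_up = NA_character_, runner_r = NA_real_,
                tie = FALSE, unassignable = TRUE))
  r <- apply(tpl, 1L, function(t) cor(profile, t))
  best <- which.max(r)
  tie <- sum(abs(r - r[best]) < 1e-12) > 1L
  o <- order(-r)
  list(family = family, mode = rownames(tpl)[best], r = r[[best]],
       runner_up = rownames(tpl)[o[2L]], runner_r = r[[o[2L]]],
       tie = tie, unassignable = FALSE)
}

#' Assign every gene in an expression set to a dynamic mode
#' @param se expression `SummarizedExperiment`.
#' @param family "rate" or "magnitude".
#' @param stat replicate-collapsing statistic.
#' @return data.frame with gene_id, family, mode, r, runner_up, runner_r,
#'   tie, unassignable.
#' @export
assign_modes <- function(se, family = c("rate", "magnitude"),
                         stat = c("mean", "median")) {
  family <- match.arg(family); stat <- match.arg(stat)
  ids <- rownames(se)
  res <- lapply(ids, function(g) assign_mode(timecourse(se, g), family, stat))
  data.frame(gene_id = ids, family = family,
             mode = vapply(res, `[[`, character(1L), "mode"),
             r = vapply(res, `[[`, numeric(1L), "r"),
             runner_up = vapply(res, `[[`, character(1L), "runner_up"),
             runner_r = vapply(res, `[[`, numeric(1L), "runner_r"),
             tie = vapply(res, `[[`, logical(1L), "tie"),
             unassignable = vapply(res, `[[`, logical(1L), "unassignable"),
             row.names = NULL, stringsAsFactors = FALSE)
}
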