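#' Per-vial marker inheritance summary
#'
#' Computes, per vial, the fraction of scored flies positive for a
#' fluorescent marker, then averages across vials (each F1 germline counts
#' once, regardless of how many flies it produced) — the convention used
#' when reporting drive inheritance with vial-to-vial standard deviation.
#'
#' @param table a scoring table (see [simulate_cross()]).
#' @param marker `"dsred"` (Cas9 transgene) or `"gfp"` (gRNA transgene).
#' @return object of class `inheritance_summary`: list with `per_vial`
#'   (data.frame `vial`, `fraction`, `n_flies`), `mean`, `sd`, `n_vials`,
#'   `total_flies`.  Vials with zero flies are excluded with a warning.
#' @examples
#' sc <- cross_scheme()
#' s <- inheritance_summary(simulate_cross(sc, germline_timing(
#'   q_late = 1, c_late = 0.8), seed = 2), "gfp")
#' s$mean
#' @export
inheritance_summary <- function(table, marker = c("gfp", "dsred")) {
  marker <- match.arg(marker)
  if (nrow(table) == 0) stop("empty scoring table", call. = FALSE)
  tot <- tapply(table$count, table$vial, sum)
  pos <- tapply(table$count * (table[[marker]] == "+"), table$vial, sum)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " empty vial(s) excluded from the summary")
    tot <- tot[!empty]; pos <- pos[!empty]
  }
  if (length(tot) == 0) stop("no non-empty vials", call. = FALSE)
  per_vial <- data.frame(vial = names(tot),
                         fraction = as.numeric(pos / tot),
                         n_flies = as.numeric(tot))
  structure(list(per_vial = per_vial,
                 marker = marker,
                 mean = mean(per_vial$fraction),
                 sd = stats::sd(per_vial$fraction),
                 n_vials = nrow(per_vial),
                 total_flies = sum(per_vial$n_flies)),
            class = "inheritance_summary")
}

#' @export
print.inheritance_summary <- function(x, ...) {
  cat(sprintf(
    "<inheritance_summary> %s: mean %.1f%% (sd %.1f) over %d vials, %d flies\n",
    x$marker, 100 * x$mean, 100 * ifelse(is.na(x$sd), 0, x$sd),
    x$n_vials, x$total_flies))
  invisible(x)
}

#' Classify paired inheritance points about the diagonal
#'
#' For scatter points of (x, y) inheritance pairs (e.g. Cas9 vs gRNA
#' conversion per vial), reports the fractions falling over, on, and under
#' the midline `y = x`.
#'
#' @param points two-column matrix or data.frame of (x, y) pairs in
#'   `[0, 1]^2`.
#' @param tol half-width of the "on the diagonal" band.
#' @return named numeric vector `c(over =, on =, under =)`, summing to 1.
#' @export
diagonal_classification <- function(points, tol = 0) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("no points", call. = FALSE)
  if (any(points < 0 | points > 1)) stop("points must lie in [0,1]^2")
  d <- points[, 2] - points[, 1]
  c(over = mean(d > tol),
    on = mean(abs(d) <= tol),
    under = mean(-d > tol))
}
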