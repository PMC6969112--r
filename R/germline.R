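# Germline homing, gamete formation and maternal-deposition transforms.
#
# Distributions over genotypes or haplotypes are named numeric vectors
# (names = codes) summing to 1.  All expansions are exact products over
# independent per-allele branchings; no renormalization is ever applied.

dist1 <- function(code) stats::setNames(1, code)

collapse_dist <- function(p) {
  # sum probabilities of duplicated outcomes; outcome names sorted so the
  # returned distribution has a deterministic layout
  if (anyDuplicated(names(p))) p <- tapply(p, names(p), sum)
  out <- as.numeric(p)
  names(out) <- names(p)
  out <- out[out > 0]
  out[order(names(out))]
}

# positions (hap index, locus) of W alleles cleavable by the drive carried
# in this genotype: both components present and the homolog carries the T
# template at that locus.
competent_positions <- function(haps, architecture) {
  n <- architecture$n_loci
  st <- lapply(haps, hap_states, n_loci = n)
  if (identical(st[[2]], "Y")) return(NULL)          # hemizygous male
  has_cas9 <- any(vapply(cas9_loci(architecture),
                         function(i) any(st[[1]][i] == "T", st[[2]][i] == "T"),
                         logical(1)))
  has_grna <- any(vapply(grna_loci(architecture),
                         function(i) any(st[[1]][i] == "T", st[[2]][i] == "T"),
                         logical(1)))
  if (!has_cas9 || !has_grna) return(NULL)
  pos <- NULL
  for (h in 1:2) for (i in seq_len(n))
    if (st[[h]][i] == "W" && st[[3 - h]][i] == "T")
      pos <- rbind(pos, c(h, i))
  pos
}

#' Germline homing transform
#'
#' Applies the drive cascade to a parent's germline genotype.  A wild-type
#' allele at a drive locus is *drive-competent* when the genotype carries at
#' least one Cas9 source and one gRNA source (one fused element for a full
#' drive) and the homologous chromosome carries the transgene template at
#' that locus.  Each competent allele, independently: is cleaved with
#' probability `q[locus, sex]`; a cleaved allele is converted to the
#' transgene `T` (homology-directed repair off the homolog) with probability
#' `c[locus, sex]`, and otherwise end-joins to an in-frame resistant `R`
#' with probability `rho` or an out-of-frame `B` otherwise.  Hemizygous
#' X-linked males have no homolog, so no conversion is possible and the
#' genotype passes through unchanged.
#'
#' @param genotype genotype code, e.g. `"TA-WB/WA-TB|F"`.
#' @param params a [cube_params()].
#' @param architecture a [drive_architecture()]; defaults to the one in
#'   `params`.
#' @return named numeric vector: exact distribution over post-conversion
#'   genotype codes.
#' @examples
#' a <- drive_architecture("full_GD")
#' germline_transform("T/W|F", cube_params(a, q = 1, c_conv = 0.9))
#' @export
germline_transform <- function(genotype, params,
                               architecture = params$architecture) {
  g <- split_genotype(genotype)
  haps <- g$haps
  pos <- competent_positions(haps, architecture)
  if (is.null(pos)) return(dist1(genotype))
  sx <- g$sex
  n <- architecture$n_loci
  rho <- params$rho
  out <- stats::setNames(numeric(0), character(0))
  # product expansion over per-position outcomes {W, T, R, B}
  k <- nrow(pos)
  outcomes <- expand.grid(rep(list(STATE_CODES), k), stringsAsFactors = FALSE)
  st <- lapply(haps, hap_states, n_loci = n)
  for (r in seq_len(nrow(outcomes))) {
    pr <- 1
    st2 <- st
    for (j in seq_len(k)) {
      h <- pos[j, 1]; i <- pos[j, 2]
      q <- params$q[i, sx]; cc <- params$c[i, sx]
      w <- switch(outcomes[r, j],
                  W = 1 - q,
                  T = q * cc,
                  R = q * (1 - cc) * rho,
                  B = q * (1 - cc) * (1 - rho))
      if (w == 0) { pr <- 0; break }
      pr <- pr * w
      st2[[h]][i] <- outcomes[r, j]
    }
    if (pr == 0) next
    code <- genotype_code(hap_code(st2[[1]], n), hap_code(st2[[2]], n), sx, n)
    out <- c(out, stats::setNames(pr, code))
  }
  collapse_dist(out)
}

#' Gamete distribution of a (post-conversion) genotype
#'
#' Standard Mendelian segregation: each haplotype is transmitted with
#' probability 1/2.  For two-locus systems, recombinant haplotypes form with
#' the architecture's recombination fraction.  X-linked males transmit their
#' X haplotype or a drive-free Y, each with probability 1/2 (which also sets
#' offspring sex).
#'
#' @inheritParams germline_transform
#' @return named numeric vector over haplotype codes (including `"Y"` for
#'   X-linked males), summing to 1.
#' @export
gamete_distribution <- function(genotype, architecture) {
  g <- split_genotype(genotype)
  n <- architecture$n_loci
  st <- lapply(g$haps, hap_states, n_loci = n)
  if (identical(st[[2]], "Y"))
    return(collapse_dist(stats::setNames(
      c(0.5, 0.5), c(hap_code(st[[1]], n), "Y"))))
  if (n == 1L)
    return(collapse_dist(stats::setNames(
      c(0.5, 0.5), c(hap_code(st[[1]], n), hap_code(st[[2]], n)))))
  rf <- architecture$recomb_fraction
  par1 <- hap_code(st[[1]], n); par2 <- hap_code(st[[2]], n)
  rec1 <- hap_code(c(st[[1]][1], st[[2]][2]), n)
  rec2 <- hap_code(c(st[[2]][1], st[[1]][2]), n)
  collapse_dist(stats::setNames(
    c((1 - rf) / 2, (1 - rf) / 2, rf / 2, rf / 2),
    c(par1, par2, rec1, rec2)))
}

#' Maternal-deposition transform on a zygote
#'
#' Mothers carrying both drive components load Cas9/gRNA ribonucleoprotein
#' into the egg.  Each wild-type allele of the zygote at a drive locus is
#' then cleaved with probability `d[locus]` and repaired by end-joining only
#' (`R` with probability `rho`, else `B`); deposition never performs
#' homology-directed repair, so it creates resistant alleles, not
#' conversions.  Inactive (identity) when the mother lacks either component.
#'
#' @param zygote genotype code of the offspring zygote.
#' @param mother genotype code of the dam.
#' @inheritParams germline_transform
#' @return named numeric vector: exact distribution over genotype codes.
#' @export
deposition_transform <- function(zygote, mother, params,
                                 architecture = params$architecture) {
  if (!has_both_components(mother, architecture)) return(dist1(zygote))
  deposition_on_zygote(zygote, params, architecture)
}

# deposition given an active mother (used by the cube builder, which knows
# activity from the mother's row)
deposition_on_zygote <- function(zygote, params, architecture) {
  g <- split_genotype(zygote)
  n <- architecture$n_loci
  st <- lapply(g$haps, hap_states, n_loci = n)
  pos <- NULL
  for (h in seq_along(st)) {
    if (identical(st[[h]], "Y")) next
    for (i in seq_len(n)) if (st[[h]][i] == "W") pos <- rbind(pos, c(h, i))
  }
  if (is.null(pos)) return(dist1(zygote))
  rho <- params$rho
  k <- nrow(pos)
  outcomes <- expand.grid(rep(list(c("W", "R", "B")), k),
                          stringsAsFactors = FALSE)
  out <- stats::setNames(numeric(0), character(0))
  for (r in seq_len(nrow(outcomes))) {
    pr <- 1
    st2 <- st
    for (j in seq_len(k)) {
      h <- pos[j, 1]; i <- pos[j, 2]
      d <- params$d[i]
      w <- switch(outcomes[r, j],
                  W = 1 - d, R = d * rho, B = d * (1 - rho))
      if (w == 0) { pr <- 0; break }
      pr <- pr * w
      st2[[h]][i] <- outcomes[r, j]
    }
    if (pr == 0) next
    code <- genotype_code(hap_code(st2[[1]], n), hap_code(st2[[2]], n),
                          g$sex, n)
    out <- c(out, stats::setNames(pr, code))
  }
  collapse_dist(out)
}
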