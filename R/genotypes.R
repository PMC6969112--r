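# Genotype string codes
#
# Haplotypes are written as one state letter per locus, suffixed with the
# locus letter for multi-locus systems: "T" (full drive) or "TA-WB" (split
# drive, state T at locus A, W at locus B).  The Y chromosome of an X-linked
# male is written "Y" and carries no drive alleles.  A genotype is
# "hap1/hap2|F" or "hap1/hap2|M" with the two haplotypes in canonical order
# (lexicographic by per-locus state code W < T < R < B; Y always second).

hap_code <- function(states, n_loci) {
  if (identical(states, "Y")) return("Y")
  if (n_loci == 1L) return(states)
  paste0(states, LETTERS[seq_len(n_loci)], collapse = "-")
}

hap_states <- function(hap, n_loci) {
  if (hap == "Y") return("Y")
  if (n_loci == 1L) return(hap)
  substr(strsplit(hap, "-", fixed = TRUE)[[1]], 1L, 1L)
}

hap_rank <- function(states) {
  # scalar rank used for canonical ordering of a haplotype pair
  if (identical(states, "Y")) return(Inf)
  sum(match(states, STATE_CODES) * 5 ^ (rev(seq_along(states)) - 1))
}

genotype_code <- function(hap1, hap2, sex, n_loci) {
  r1 <- hap_rank(hap_states(hap1, n_loci))
  r2 <- hap_rank(hap_states(hap2, n_loci))
  if (r2 < r1) { tmp <- hap1; hap1 <- hap2; hap2 <- tmp }
  paste0(hap1, "/", hap2, "|", sex)
}

split_genotype <- function(code) {
  # returns list(haps = c(h1, h2), sex = "F"/"M"); core code has no sex tag
  parts <- strsplit(code, "|", fixed = TRUE)[[1]]
  sex <- if (length(parts) == 2L) parts[2] else NA_character_
  list(haps = strsplit(parts[1], "/", fixed = TRUE)[[1]], sex = sex)
}

strip_sex <- function(code) sub("\\|[FM]$", "", code)

#' Canonicalize a genotype code
#'
#' Reorders the haplotype pair into the documented canonical order
#' (lexicographic by per-locus state code `W < T < R < B`; `Y` last), so
#' that e.g. `"T/W|F"` and `"W/T|F"` name the same genotype.
#' @param code genotype code with sex tag.
#' @param architecture a [drive_architecture()].
#' @return the canonical code.
#' @export
canonical_genotype <- function(code, architecture) {
  g <- split_genotype(code)
  genotype_code(g$haps[1], g$haps[2], g$sex, architecture$n_loci)
}

#' Enumerate haplotypes of an architecture
#'
#' All combinations of the four allele states (`W`, `T`, `R`, `B`) over the
#' architecture's drive loci, in lexicographic order by state code
#' `W < T < R < B`.
#'
#' @param architecture a [drive_architecture()].
#' @return character vector of haplotype codes.
#' @export
enumerate_haplotypes <- function(architecture) {
  n <- architecture$n_loci
  grids <- rev(expand.grid(rep(list(STATE_CODES), n),
                           stringsAsFactors = FALSE))
  apply(as.matrix(grids), 1L, hap_code, n_loci = n)
}

#' Enumerate all genotypes of an architecture
#'
#' Diploid genotypes are unordered haplotype pairs in the documented
#' canonical order.  For X-linked architectures males are hemizygous: their
#' second "haplotype" is the drive-free Y.
#'
#' @param architecture a [drive_architecture()].
#' @param sex `"F"`, `"M"`, or `"both"`.
#' @return character vector of genotype codes, stable across calls: pairs
#'   ordered by (first haplotype, second haplotype) rank, females before
#'   males when `sex = "both"`.
#' @examples
#' length(enumerate_genotypes(drive_architecture("full_GD"), "F"))   # 10
#' length(enumerate_genotypes(drive_architecture("full_GDX"), "M"))  # 4
#' @export
enumerate_genotypes <- function(architecture, sex = c("both", "F", "M")) {
  sex <- match.arg(sex)
  haps <- enumerate_haplotypes(architecture)
  n <- length(haps)
  pair_codes <- function(sx) {
    out <- character(0)
    for (i in seq_len(n))
      for (j in i:n)
        out <- c(out, paste0(haps[i], "/", haps[j], "|", sx))
    out
  }
  female <- pair_codes("F")
  male <- if (is_x_linked(architecture))
    paste0(haps, "/Y|M") else pair_codes("M")
  switch(sex, F = female, M = male, both = c(female, male))
}

# allele content of a genotype: counts of each state per locus.
# Returns matrix [state x locus]; Y contributes nothing.
genotype_allele_counts <- function(code, architecture) {
  g <- split_genotype(code)
  n <- architecture$n_loci
  m <- matrix(0L, nrow = 4L, ncol = n,
              dimnames = list(STATE_CODES, NULL))
  for (h in g$haps) {
    st <- hap_states(h, n)
    if (identical(st, "Y")) next
    for (i in seq_len(n)) m[st[i], i] <- m[st[i], i] + 1L
  }
  m
}

# does the genotype carry >= 1 copy of `state` (optionally at `locus`)?
carries_allele <- function(code, architecture, state, locus = NULL) {
  cnt <- genotype_allele_counts(code, architecture)
  if (is.null(locus)) any(cnt[state, ] > 0) else cnt[state, locus] > 0
}

# both drive components present in this genotype?
has_both_components <- function(code, architecture) {
  cnt <- genotype_allele_counts(code, architecture)
  any(cnt["T", cas9_loci(architecture)] > 0) &&
    any(cnt["T", grna_loci(architecture)] > 0)
}
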