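#' Drive parameters for inheritance-cube construction
#'
#' Houses the per-locus, per-parental-sex probabilities of the homing
#' cascade plus maternal-deposition cleavage, the in-frame fraction of
#' end-joining repair, genotype fitness multipliers and an optional female
#' fertility rule used by suppression scenarios.
#'
#' The default parameterization reflects exploratory "ballpark" drive
#' modeling: certain cleavage (`q = 1`), perfect conversion (`c = 1`), no
#' maternal deposition (`d = 0`), all end-joining repairs in-frame
#' (`rho = 1`) and no fitness costs.
#'
#' @param architecture a [drive_architecture()].
#' @param q cleavage probability per target wild-type allele in the parental
#'   germline; scalar, per-locus vector, or `n_loci x 2` matrix with columns
#'   `F`, `M`.
#' @param c_conv conversion (homology-directed repair) probability given
#'   cleavage; same shapes as `q`.
#' @param d maternal-deposition cleavage probability per locus acting on
#'   zygotic wild-type alleles when the mother carries both drive
#'   components; scalar or per-locus vector.
#' @param rho probability that an end-joining repair is in-frame
#'   (function-preserving `R`) rather than out-of-frame (`B`).
#' @param omega named vector of relative fitness multipliers per genotype
#'   code (missing genotypes default to 1); used by the population model as
#'   fecundity and mate-choice weights.
#' @param fertility_rule optional `function(genotype_code, architecture)`
#'   returning `FALSE` for sterile female genotypes (suppression mode).
#' @return object of class `cube_params`; `q` and `c` are stored as
#'   `n_loci x 2` matrices with columns `F` and `M`.
#' @examples
#' cube_params(drive_architecture("full_GD"), q = 1, c_conv = 0.9)
#' @export
cube_params <- function(architecture, q = 1, c_conv = 1, d = 0, rho = 1,
                        omega = NULL, fertility_rule = NULL) {
  n <- architecture$n_loci
  as_mat <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n, 2L)))
        stop(nm, " matrix must be n_loci x 2 (F, M)", call. = FALSE)
      m <- x
    } else if (length(x) %in% c(1L, n)) {
      m <- matrix(rep(x, length.out = n), nrow = n, ncol = 2L)
    } else stop("bad shape for ", nm, call. = FALSE)
    dimnames(m) <- list(NULL, c("F", "M"))
    if (any(m < 0 | m > 1)) stop(nm, " must lie in [0,1]", call. = FALSE)
    m
  }
  d <- rep(d, length.out = n)
  if (any(d < 0 | d > 1)) stop("d must lie in [0,1]", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0,1]", call. = FALSE)
  if (!is.null(omega) && any(omega < 0))
    stop("omega must be non-negative", call. = FALSE)
  structure(
    list(architecture = architecture,
         q = as_mat(q, "q"), c = as_mat(c_conv, "c"), d = d, rho = rho,
         omega = omega, fertility_rule = fertility_rule),
    class = "cube_params"
  )
}

# fitness multiplier lookup with default 1
omega_of <- function(params, codes) {
  w <- rep(1, length(codes))
  if (!is.null(params$omega)) {
    hit <- match(codes, names(params$omega))
    w[!is.na(hit)] <- params$omega[hit[!is.na(hit)]]
  }
  w
}

#' Sterility rule targeting one locus (suppression drives)
#'
#' Builds a `fertility_rule` for [cube_params()]: a female is fertile iff
#' she carries at least one functional allele (wild-type `W` or in-frame
#' resistant `R`) at the target locus.  The drive transgene `T` and
#' out-of-frame `B` alleles are non-functional there, so drive homozygotes
#' are sterile — the suppression mechanism.
#'
#' @param locus index of the targeted fertility locus; defaults to the gRNA
#'   locus of a split drive or the fused locus of a full drive.
#' @return a function usable as `fertility_rule`.
#' @export
fertility_rule_functional <- function(locus = NULL) {
  force(locus)
  function(code, architecture) {
    loc <- if (is.null(locus)) max(grna_loci(architecture)) else locus
    cnt <- genotype_allele_counts(code, architecture)
    (cnt["W", loc] + cnt["R", loc]) > 0
  }
}
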