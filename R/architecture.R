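# Allele state codes, ordered W < T < R < B for canonicalization.
STATE_CODES <- c("W", "T", "R", "B")

#' Drive architectures
#'
#' A drive architecture describes where the drive machinery sits in the
#' genome: a *full drive* carries Cas9 and its guide RNAs as a single fused
#' element at one locus, while a *split (trans-complementing) drive* keeps
#' the Cas9 cassette and the tandem-gRNA cassette at two separate loci, each
#' of which homes into its own wild-type counterpart only when both are
#' present in the same individual.  Six named configurations are supported:
#'
#' * `full_GD` — fused element, one autosomal locus.
#' * `full_GDX` — fused element, one X-linked locus (males hemizygous).
#' * `tGD_linked` — Cas9 + gRNA loci linked on one autosome
#'   (recombination fraction defaults to 0, complete linkage).
#' * `tGDc` — the two loci on separate autosomes (recombination fixed at 1/2).
#' * `tGDX_linked` — both loci linked on the X.
#' * `tGDXc` — two unlinked X loci (recombination fixed at 1/2).
#'
#' @param name one of the six architecture names above.
#' @param recomb_fraction recombination fraction between the two loci of a
#'   linked split drive, in `[0, 0.5]`.  Ignored (forced to 0.5) for the
#'   unlinked `tGDc`/`tGDXc` configurations and meaningless for full drives.
#' @return an object of class `drive_architecture` with fields `name`,
#'   `n_loci`, `roles` (per-locus role: `cas9_site`, `grna_site` or
#'   `fused_site`), `chromosome` (`"autosome"` or `"X"`) and
#'   `recomb_fraction`.
#' @examples
#' drive_architecture("tGD_linked")
#' drive_architecture("full_GDX")
#' @export
drive_architecture <- function(name, recomb_fraction = NULL) {
  specs <- list(
    full_GD     = list(roles = "fused_site", chromosome = "autosome", rf = 0),
    full_GDX    = list(roles = "fused_site", chromosome = "X",        rf = 0),
    tGD_linked  = list(roles = c("cas9_site", "grna_site"),
                       chromosome = "autosome", rf = 0),
    tGDc        = list(roles = c("cas9_site", "grna_site"),
                       chromosome = "autosome", rf = 0.5),
    tGDX_linked = list(roles = c("cas9_site", "grna_site"),
                       chromosome = "X", rf = 0),
    tGDXc       = list(roles = c("cas9_site", "grna_site"),
                       chromosome = "X", rf = 0.5)
  )
  if (!name %in% names(specs))
    stop("unknown architecture name: ", name, call. = FALSE)
  sp <- specs[[name]]
  rf <- sp$rf
  if (name %in% c("tGDc", "tGDXc")) {
    if (!is.null(recomb_fraction) && recomb_fraction != 0.5)
      stop(name, " has unlinked loci; recomb_fraction is fixed at 0.5",
           call. = FALSE)
  } else if (!is.null(recomb_fraction)) {
    if (!is.numeric(recomb_fraction) || recomb_fraction < 0 ||
        recomb_fraction > 0.5)
      stop("recomb_fraction must lie in [0, 0.5]", call. = FALSE)
    rf <- recomb_fraction
  }
  structure(
    list(name = name, n_loci = length(sp$roles), roles = sp$roles,
         chromosome = sp$chromosome, recomb_fraction = rf),
    class = "drive_architecture"
  )
}

#' @export
print.drive_architecture <- function(x, ...) {
  cat("<drive_architecture> ", x$name, "\n",
      "  loci: ", paste(x$roles, collapse = ", "),
      " on ", x$chromosome, "\n",
      "  recombination fraction: ", x$recomb_fraction, "\n", sep = "")
  invisible(x)
}

is_x_linked <- function(architecture) architecture$chromosome == "X"

# Locus indices carrying a Cas9 source / a gRNA source when occupied by T.
cas9_loci <- function(architecture)
  which(architecture$roles %in% c("cas9_site", "fused_site"))
grna_loci <- function(architecture)
  which(architecture$roles %in% c("grna_site", "fused_site"))
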