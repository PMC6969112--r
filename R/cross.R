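# F0 -> F1 -> F2 fly cross simulation with cleavage-timing structure.
#
# The generative model separates two windows in which the drive can act in
# an F1 individual whose mother deposited Cas9/gRNA ribonucleoprotein:
#   * zygote stage: each wild-type allele at a drive locus is cleaved with
#     probability z and repaired by end-joining, fixing a single indel
#     identity clonally across the entire germline (no conversion possible
#     afterwards at that allele);
#   * germline development: the germline descends from k primordial
#     precursor ("pole") cells; each cell independently resolves each
#     remaining drive-competent wild-type allele (cleave q_late, convert
#     c_late, otherwise an end-joining indel), so a vial can show at most k
#     distinct late indels per locus.
# Each F2 offspring samples one precursor cell uniformly, then a gamete.

#' Indel spectrum
#'
#' Categorical identities for end-joining resistant alleles: a few recurrent
#' labels plus a "tail" of always-novel singleton identities, mirroring the
#' observation that a handful of indels recur across independent germlines
#' while the rest are unique.
#'
#' @param labels character vector of recurrent indel identities.
#' @param probs their probabilities.
#' @param tail_prob probability mass of novel singleton identities; the
#'   three arguments must satisfy `sum(probs) + tail_prob == 1`.
#' @return object of class `indel_spectrum`.
#' @examples
#' indel_spectrum(c("wA", "wB", "wC"), c(0.5, 0.25, 0.18), tail_prob = 0.07)
#' @export
indel_spectrum <- function(labels, probs, tail_prob = 0) {
  if (length(labels) != length(probs)) stop("labels/probs length mismatch")
  if (anyDuplicated(labels)) stop("indel labels must be unique")
  if (any(probs < 0) || tail_prob < 0 ||
      abs(sum(probs) + tail_prob - 1) > 1e-9)
    stop("probs + tail_prob must sum to 1", call. = FALSE)
  structure(list(labels = labels, probs = probs, tail_prob = tail_prob),
            class = "indel_spectrum")
}

# draw n indel identities; the singleton tail yields fresh labels from a
# counter kept in `env` so they are never repeated within a simulation
draw_indels <- function(spectrum, n, env) {
  k <- length(spectrum$labels)
  pick <- sample.int(k + 1L, n, replace = TRUE,
                     prob = c(spectrum$probs, spectrum$tail_prob))
  out <- character(n)
  rec <- pick <= k
  out[rec] <- spectrum$labels[pick[rec]]
  n_new <- sum(!rec)
  if (n_new > 0) {
    out[!rec] <- sprintf("u%04d", env$singleton_counter + seq_len(n_new))
    env$singleton_counter <- env$singleton_counter + n_new
  }
  out
}

#' Germline timing parameters
#'
#' @param z probability of a zygotic deposition-cleavage event per target
#'   wild-type allele (scalar or per-locus); forced to 0 when the F0 mother
#'   does not carry both drive components.
#' @param k number of primordial germline precursor cells (default 3,
#'   the canonical pole-cell count of the early fly embryo).
#' @param q_late,c_late per-precursor-cell cleavage and conversion
#'   probabilities during germline development (scalar or per-locus).
#' @param rho in-frame fraction of end-joining repairs.
#' @param spectra named list of [indel_spectrum()] per locus letter
#'   (`A`, `B`); a single spectrum is recycled to all loci.
#' @return object of class `germline_timing`.
#' @export
germline_timing <- function(z = 0, k = 3L, q_late = 1, c_late = 1, rho = 1,
                            spectra = indel_spectrum(character(0),
                                                     numeric(0), 1)) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  chk <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(nm, " must lie in [0,1]", call. = FALSE); x
  }
  if (inherits(spectra, "indel_spectrum")) spectra <- list(A = spectra,
                                                          B = spectra)
  structure(list(z = chk(z, "z"), k = as.integer(k),
                 q_late = chk(q_late, "q_late"),
                 c_late = chk(c_late, "c_late"), rho = chk(rho, "rho"),
                 spectra = spectra),
            class = "germline_timing")
}

#' Cross scheme
#'
#' Which F0 parent carries which drive component, whether the components are
#' coupled on a single F0 chromosome, and the sex of the F1 germline scored.
#' The strong maternal effect arises only in the `coupled` scheme with the
#' drive-bearing F0 parent being the mother: only then is the zygotic
#' deposition channel active in the F1.
#'
#' @param f0_cas9_parent,f0_grna_parent `"father"` or `"mother"`.
#' @param coupled both elements on one F0 chromosome (requires both from
#'   the same parent).
#' @param f1_sex_scored `"female"` or `"male"`; male germline scoring is
#'   only valid for autosomal architectures (X-linked males are hemizygous,
#'   so no conversion is possible there).
#' @param architecture a two-locus [drive_architecture()].
#' @return object of class `cross_scheme`.
#' @export
cross_scheme <- function(f0_cas9_parent = "father",
                         f0_grna_parent = "mother",
                         coupled = FALSE, f1_sex_scored = "female",
                         architecture = drive_architecture("tGDX_linked")) {
  f0_cas9_parent <- match.arg(f0_cas9_parent, c("father", "mother"))
  f0_grna_parent <- match.arg(f0_grna_parent, c("father", "mother"))
  f1_sex_scored <- match.arg(f1_sex_scored, c("female", "male"))
  if (architecture$n_loci != 2L)
    stop("cross schemes require a two-locus (split-drive) architecture")
  if (coupled && f0_cas9_parent != f0_grna_parent)
    stop("coupled elements must come from a single F0 parent")
  if (f1_sex_scored == "male" && is_x_linked(architecture))
    stop("male F1 germline scoring requires an autosomal architecture")
  structure(list(f0_cas9_parent = f0_cas9_parent,
                 f0_grna_parent = f0_grna_parent, coupled = coupled,
                 f1_sex_scored = f1_sex_scored, architecture = architecture),
            class = "cross_scheme")
}

# --- internal genotype bookkeeping for the cross simulator -----------------
# A germline-cell genotype is a 2 x n_loci state matrix plus a parallel
# label matrix holding indel identities of R/B alleles.

f1_zygote_states <- function(scheme) {
  if (scheme$coupled)
    rbind(c("T", "T"), c("W", "W"))
  else  # Cas9 hap from one parent, gRNA hap from the other
    rbind(c("T", "W"), c("W", "T"))
}

maternal_deposition_active <- function(scheme) {
  scheme$coupled && scheme$f0_cas9_parent == "mother"
}

cell_competent <- function(st, locus) {
  # both components somewhere, W at locus with T template on the homolog
  any(st[, 1] == "T") && any(st[, 2] == "T") &&
    any(st[, locus] == "W") && any(st[, locus] == "T")
}

#' Simulate a scored F0 -> F1 -> F2 cross
#'
#' Each vial holds the F2 progeny of a single F1 parent (sampled per the
#' scheme) outcrossed to wild type.  Offspring phenotypes derive from
#' genotype: `dsred` marks the Cas9 transgene (locus A), `gfp` the gRNA
#' transgene (locus B); the `body` and `eye` phenotype columns are mutant
#' when no functional allele (`W` or in-frame `R`) of the respective target
#' gene is present among the copies carried.  Male F2 records carrying
#' end-joining resistant alleles receive their indel identities in the
#' `indel` column, formatted `"A=yB;B=wA"` by locus.
#'
#' @param scheme a [cross_scheme()].
#' @param timing a [germline_timing()].
#' @param n_vials number of F1 parents (vials).
#' @param n_offspring_per_vial F2 progeny scored per vial.
#' @param seed integer seed; the simulation is fully reproducible.
#' @param experiment experiment identifier written to the table.
#' @return a `data.frame` scoring table with columns `experiment, vial, sex,
#'   dsred, gfp, body, eye, count, indel`.
#' @examples
#' sc <- cross_scheme(coupled = TRUE, f0_cas9_parent = "mother",
#'                    f0_grna_parent = "mother")
#' tab <- simulate_cross(sc, germline_timing(z = 1), n_vials = 3,
#'                       n_offspring_per_vial = 30, seed = 1)
#' @export
simulate_cross <- function(scheme, timing = germline_timing(),
                           n_vials = 10L, n_offspring_per_vial = 50L,
                           seed = 1L, experiment = "sim") {
  stopifnot(n_vials >= 1, n_offspring_per_vial >= 1)
  set.seed(seed)
  arch <- scheme$architecture
  n <- arch$n_loci
  z <- rep(timing$z, length.out = n)
  q_late <- rep(timing$q_late, length.out = n)
  c_late <- rep(timing$c_late, length.out = n)
  rho <- timing$rho
  rf <- arch$recomb_fraction
  xl <- is_x_linked(arch)
  f1_female <- scheme$f1_sex_scored == "female"
  depo <- maternal_deposition_active(scheme)
  env <- new.env(); env$singleton_counter <- 0L

  rows <- vector("list", n_vials)
  for (v in seq_len(n_vials)) {
    st0 <- f1_zygote_states(scheme)
    lb0 <- matrix(NA_character_, 2, n)
    # (i) zygotic deposition-cleavage: clonal, end-joining only
    if (depo) {
      for (i in seq_len(n)) for (h in 1:2) {
        if (st0[h, i] == "W" && stats::runif(1) < z[i]) {
          st0[h, i] <- if (stats::runif(1) < rho) "R" else "B"
          lb0[h, i] <- draw_indels(timing$spectra[[LETTERS[i]]], 1L, env)
        }
      }
    }
    # (ii) k precursor cells resolve remaining competent alleles
    cells <- vector("list", timing$k)
    for (cell in seq_len(timing$k)) {
      st <- st0; lb <- lb0
      if (!(xl && !f1_female)) {  # hemizygous X males cannot convert
        for (i in seq_len(n)) {
          if (!cell_competent(st, i)) next
          h <- which(st[, i] == "W")
          for (hh in h) {
            if (stats::runif(1) >= q_late[i]) next
            if (stats::runif(1) < c_late[i]) {
              st[hh, i] <- "T"
            } else {
              st[hh, i] <- if (stats::runif(1) < rho) "R" else "B"
              lb[hh, i] <- draw_indels(timing$spectra[[LETTERS[i]]], 1L, env)
            }
          }
        }
      }
      cells[[cell]] <- list(st = st, lb = lb)
    }
    # (iii) F2 offspring: precursor cell -> gamete -> + wild-type gamete
    m <- n_offspring_per_vial
    cell_pick <- sample.int(timing$k, m, replace = TRUE)
    o_sex <- character(m); o_dsred <- character(m); o_gfp <- character(m)
    o_body <- character(m); o_eye <- character(m)
    o_indel <- rep(NA_character_, m)
    for (o in seq_len(m)) {
      cl <- cells[[cell_pick[o]]]
      hap_pick <- sample.int(2L, 1L)
      gam_st <- cl$st[hap_pick, ]
      gam_lb <- cl$lb[hap_pick, ]
      if (n == 2L && rf > 0 && stats::runif(1) < rf) {   # recombination
        other <- 3L - hap_pick
        gam_st[2] <- cl$st[other, 2]; gam_lb[2] <- cl$lb[other, 2]
      }
      if (xl && f1_female) {
        # father's W-bearing X or his Y decides offspring sex
        sex <- if (stats::runif(1) < 0.5) "F" else "M"
        paternal_w <- sex == "F"
      } else {
        sex <- if (stats::runif(1) < 0.5) "F" else "M"
        paternal_w <- TRUE       # autosomal: wild-type gamete either sex
      }
      has_T <- gam_st == "T"
      func <- gam_st %in% c("W", "R")
      if (paternal_w) func <- rep(TRUE, n)   # paternal W restores function
      o_sex[o] <- sex
      o_dsred[o] <- if (has_T[1]) "+" else "-"
      o_gfp[o] <- if (has_T[2]) "+" else "-"
      o_body[o] <- if (func[1]) "wild" else "mutant"
      o_eye[o] <- if (func[2]) "wild" else "mutant"
      if (sex == "M") {
        lab <- which(gam_st %in% c("R", "B") & !is.na(gam_lb))
        if (length(lab) > 0)
          o_indel[o] <- paste0(LETTERS[lab], "=", gam_lb[lab],
                               collapse = ";")
      }
    }
    key <- paste(o_sex, o_dsred, o_gfp, o_body, o_eye,
                 ifelse(is.na(o_indel), "", o_indel), sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    agg <- data.frame(
      experiment = experiment, vial = v,
      sex = vapply(parts, `[`, "", 1L),
      dsred = vapply(parts, `[`, "", 2L),
      gfp = vapply(parts, `[`, "", 3L),
      body = vapply(parts, `[`, "", 4L),
      eye = vapply(parts, `[`, "", 5L),
      count = as.integer(cnt),
      indel = vapply(parts, function(p)
        if (length(p) >= 6 && nzchar(p[6])) p[6] else NA_character_, ""),
      stringsAsFactors = FALSE)
    rows[[v]] <- agg
  }
  out <- do.call(rbind, rows)
  out <- out[, c("experiment", "vial", "sex", "dsred", "gfp", "body",
                 "eye", "count", "indel")]
  rownames(out) <- NULL
  out
}

#' Per-vial distinct resistant-allele tally
#'
#' Counts the distinct indel identities recovered per vial at one locus from
#' indel-labeled male records — the statistic used to infer when cleavage
#' happened: a single identity per vial indicates one clonal zygotic event,
#' while up to `k` identities indicate events in the `k` germline precursor
#' cells.
#'
#' @param table a scoring table (see [simulate_cross()]).
#' @param locus locus letter, `"A"` or `"B"`.
#' @return `data.frame` with columns `vial`, `n_distinct`, `n_sampled`.
#' @export
distinct_indel_tally <- function(table, locus = "B") {
  pat <- paste0("(^|;)", locus, "=([^;]+)")
  vials <- sort(unique(table$vial))
  out <- lapply(vials, function(v) {
    rows <- table[table$vial == v & !is.na(table$indel), , drop = FALSE]
    hits <- regmatches(rows$indel, regexec(pat, rows$indel))
    lab <- vapply(hits, function(h) if (length(h) >= 3) h[3] else
      NA_character_, character(1))
    keep <- !is.na(lab)
    data.frame(vial = v, n_distinct = length(unique(lab[keep])),
               n_sampled = sum(rows$count[keep]))
  })
  do.call(rbind, out)
}
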