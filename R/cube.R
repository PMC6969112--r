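# Inheritance-cube construction.
#
# The cube maps (maternal genotype, paternal genotype) to an exact
# distribution over offspring (genotype, sex).  It is assembled from the
# germline transform, gamete segregation and the maternal-deposition
# transform; rows sum to 1 by construction (products of distributions that
# each sum to 1), never by renormalization.

# expected gamete distribution of a parent: mix gamete distributions over
# the post-conversion genotype distribution.  Returns a vector over the
# architecture's haplotypes (plus "Y" for X-linked males).
parent_gamete_vector <- function(genotype, params, architecture, haps) {
  post <- germline_transform(genotype, params, architecture)
  idx <- c(haps, "Y")
  acc <- stats::setNames(numeric(length(idx)), idx)
  for (g in names(post)) {
    gd <- gamete_distribution(g, architecture)
    acc[names(gd)] <- acc[names(gd)] + post[[g]] * gd
  }
  acc
}

# deposition matrix over a genotype index: D[zygote, post] for an active
# mother.  Rows of inactive mothers use the identity instead.
deposition_matrix <- function(codes, params, architecture) {
  n <- length(codes)
  D <- matrix(0, n, n, dimnames = list(codes, codes))
  for (z in codes) {
    dz <- deposition_on_zygote(z, params, architecture)
    D[z, names(dz)] <- dz
  }
  D
}

#' Build an inheritance cube
#'
#' For every (mother, father) pair the offspring distribution is the exact
#' composition of: the mother's and father's germline transforms, gamete
#' segregation (with recombination), random union of gametes, and the
#' maternal-deposition transform applied when the mother carries both drive
#' components.  Autosomal offspring are female or male with probability 1/2
#' each; X-linked offspring sex follows the paternal X-vs-Y gamete.
#'
#' @inheritParams germline_transform
#' @return an object of class `inheritance_cube`: list with `architecture`,
#'   `params`, `mothers` and `fathers` (genotype code indices), `offspring`
#'   (sex-tagged genotype index) and `tab`, the array
#'   `[mother, father, offspring]` of probabilities.
#' @examples
#' a <- drive_architecture("full_GD")
#' cube <- build_cube(a, cube_params(a, q = 1, c_conv = 0.9, rho = 1))
#' cube$tab["T/W|F", "W/W|M", ]
#' @export
build_cube <- function(architecture, params) {
  stopifnot(inherits(architecture, "drive_architecture"),
            inherits(params, "cube_params"))
  haps <- enumerate_haplotypes(architecture)
  nh <- length(haps)
  mothers <- enumerate_genotypes(architecture, "F")
  fathers <- enumerate_genotypes(architecture, "M")
  xl <- is_x_linked(architecture)

  fem_core <- strip_sex(mothers)
  male_core <- strip_sex(fathers)
  offspring <- c(mothers, fathers)

  # map a haplotype pair (i, j) to the canonical female-core index
  pair_index <- matrix(0L, nh, nh)
  for (i in seq_len(nh)) for (j in seq_len(nh)) {
    code <- genotype_code(haps[i], haps[j], "F", architecture$n_loci)
    pair_index[i, j] <- match(strip_sex(code), fem_core)
  }
  nf <- length(fem_core)

  Gm <- t(vapply(mothers, parent_gamete_vector, numeric(nh + 1L),
                 params = params, architecture = architecture, haps = haps))
  Gf <- t(vapply(fathers, parent_gamete_vector, numeric(nh + 1L),
                 params = params, architecture = architecture, haps = haps))

  Df <- deposition_matrix(mothers, params, architecture)
  dimnames(Df) <- list(fem_core, fem_core)
  if (xl) {
    Dm <- deposition_matrix(fathers, params, architecture)
    dimnames(Dm) <- list(male_core, male_core)
  }

  active <- vapply(mothers, has_both_components, logical(1),
                   architecture = architecture)

  tab <- array(0, dim = c(length(mothers), length(fathers), length(offspring)),
               dimnames = list(mothers, fathers, offspring))
  GfX <- Gf[, seq_len(nh), drop = FALSE]
  for (m in seq_along(mothers)) {
    gm <- Gm[m, seq_len(nh)]
    # M[j, k] = P(maternal gamete folds with paternal hap j into diploid k)
    M <- matrix(0, nh, nf)
    for (j in seq_len(nh)) {
      s <- rowsum(gm, pair_index[, j])
      M[j, as.integer(rownames(s))] <- s
    }
    if (xl) {
      # daughters: maternal hap x paternal X hap; sons: maternal hap + Y
      dau <- GfX %*% M                        # fathers x female cores
      son <- outer(Gf[, nh + 1L], gm)         # fathers x male cores
      if (active[m]) {
        dau <- dau %*% Df
        son <- son %*% Dm
      }
      tab[m, , ] <- cbind(dau, son)
    } else {
      zyg <- GfX %*% M                        # fathers x cores
      if (active[m]) zyg <- zyg %*% Df
      tab[m, , ] <- cbind(zyg * 0.5, zyg * 0.5)
    }
  }
  structure(list(architecture = architecture, params = params,
                 mothers = mothers, fathers = fathers,
                 offspring = offspring, tab = tab),
            class = "inheritance_cube")
}

#' @export
print.inheritance_cube <- function(x, ...) {
  cat("<inheritance_cube> ", x$architecture$name, ": ",
      length(x$mothers), " maternal x ", length(x$fathers),
      " paternal genotypes -> ", length(x$offspring),
      " offspring classes\n", sep = "")
  invisible(x)
}

#' Mendelian inheritance cube
#'
#' The cube with all drive activity switched off (`q = 0`, `d = 0`):
#' plain Mendelian segregation for the architecture.
#' @inheritParams build_cube
#' @export
mendelian_cube <- function(architecture)
  build_cube(architecture, cube_params(architecture, q = 0, c_conv = 0, d = 0))

#' Transmission rate of an allele class from a cross
#'
#' Expected fraction of offspring of the given parental pair that carry at
#' least one allele of the queried class — the quantity scored as marker
#' inheritance in drive experiments, where 50% is the Mendelian expectation
#' and anything above is super-Mendelian.
#'
#' @param cube an [build_cube()] result.
#' @param mother,father genotype codes present in the cube index.
#' @param state allele class to query (`"T"`, `"W"`, `"R"` or `"B"`).
#' @param locus optional locus restriction (index); default any locus.
#' @param offspring_sex optionally restrict to `"F"` or `"M"` offspring
#'   (the fraction is then conditional on that sex).
#' @return a probability.
#' @examples
#' a <- drive_architecture("full_GD")
#' cube <- build_cube(a, cube_params(a, q = 1, c_conv = 0.92))
#' transmission_rate(cube, "T/W|F", "W/W|M", "T")  # (1 + qc)/2 = 0.96
#' @export
transmission_rate <- function(cube, mother, father, state, locus = NULL,
                              offspring_sex = NULL) {
  if (!state %in% STATE_CODES)
    stop("unknown allele class: ", state, call. = FALSE)
  mother <- canonical_genotype(mother, cube$architecture)
  father <- canonical_genotype(father, cube$architecture)
  if (!mother %in% cube$mothers) stop("mother not in cube index")
  if (!father %in% cube$fathers) stop("father not in cube index")
  row <- cube$tab[mother, father, ]
  carry <- vapply(cube$offspring, carries_allele, logical(1),
                  architecture = cube$architecture, state = state,
                  locus = locus)
  if (is.null(offspring_sex)) return(sum(row[carry]))
  sexes <- sub("^.*\\|", "", cube$offspring)
  keep <- sexes == offspring_sex
  tot <- sum(row[keep])
  if (tot == 0) return(NA_real_)
  sum(row[carry & keep]) / tot
}

#' Export / import a cube as long-format CSV
#'
#' Columns `mother, father, offspring, sex, probability`; zero entries are
#' omitted.  Probabilities are written with 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param cube an inheritance cube.
#' @param path file path.
#' @export
write_cube_csv <- function(cube, path) {
  idx <- which(cube$tab > 0, arr.ind = TRUE)
  df <- data.frame(
    mother = cube$mothers[idx[, 1]],
    father = cube$fathers[idx[, 2]],
    offspring = strip_sex(cube$offspring[idx[, 3]]),
    sex = sub("^.*\\|", "", cube$offspring[idx[, 3]]),
    probability = sprintf("%.17g", cube$tab[idx]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$mother, df$father, df$offspring, df$sex), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @param architecture architecture of the stored cube (sets the index).
#' @export
read_cube_csv <- function(path, architecture) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(probability = "character"))
  mothers <- enumerate_genotypes(architecture, "F")
  fathers <- enumerate_genotypes(architecture, "M")
  offspring <- c(mothers, fathers)
  tab <- array(0, dim = c(length(mothers), length(fathers), length(offspring)),
               dimnames = list(mothers, fathers, offspring))
  off <- paste0(df$offspring, "|", df$sex)
  bad <- !(df$mother %in% mothers) | !(df$father %in% fathers) |
    !(off %in% offspring)
  if (any(bad))
    stop("cube CSV contains genotype codes not in this architecture",
         call. = FALSE)
  tab[cbind(match(df$mother, mothers), match(df$father, fathers),
            match(off, offspring))] <- as.numeric(df$probability)
  structure(list(architecture = architecture, params = NULL,
                 mothers = mothers, fathers = fathers,
                 offspring = offspring, tab = tab),
            class = "inheritance_cube")
}
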