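# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive the genetics by explicit enumeration of the
# full probability tree, one branch at a time, sharing no code with the
# package's vectorized cube builder.

# enumerate a parent's germline outcomes: list of (states 2 x n matrix, prob)
oracle_germline <- function(states, sex, arch, params) {
  n <- arch$n_loci
  if (any(states == "Y")) return(list(list(st = states, p = 1)))
  cas9_src <- sum(states[, which(arch$roles != "grna_site"), drop = FALSE]
                  == "T")
  grna_src <- sum(states[, which(arch$roles != "cas9_site"), drop = FALSE]
                  == "T")
  slots <- which(states == "W", arr.ind = TRUE)
  # keep only W slots whose homolog carries the template
  if (nrow(slots) > 0) {
    ok <- apply(slots, 1, function(s) states[3 - s[1], s[2]] == "T")
    slots <- slots[ok, , drop = FALSE]
  }
  if (cas9_src == 0 || grna_src == 0 || nrow(slots) == 0)
    return(list(list(st = states, p = 1)))
  res <- list(list(st = states, p = 1))
  for (s in seq_len(nrow(slots))) {
    h <- slots[s, 1]; i <- slots[s, 2]
    q <- params$q[i, sex]; cc <- params$c[i, sex]; rho <- params$rho
    branch <- list(list(x = "W", p = 1 - q),
                   list(x = "T", p = q * cc),
                   list(x = "R", p = q * (1 - cc) * rho),
                   list(x = "B", p = q * (1 - cc) * (1 - rho)))
    nxt <- list()
    for (r in res) for (b in branch) {
      if (b$p == 0) next
      st2 <- r$st; st2[h, i] <- b$x
      nxt[[length(nxt) + 1]] <- list(st = st2, p = r$p * b$p)
    }
    res <- nxt
  }
  res
}

# gametes of one (post-conversion) diploid: choose the locus-A allele from a
# haplotype, then keep or switch haplotype at locus B with the
# recombination fraction -- an intentionally different factorization from
# the package's parental/recombinant form
oracle_gametes <- function(states, arch) {
  n <- arch$n_loci
  if (any(states == "Y")) {
    xrow <- which(apply(states, 1, function(r) !any(r == "Y")))
    return(list(list(g = states[xrow, , drop = TRUE], p = 0.5),
                list(g = "Y", p = 0.5)))
  }
  if (n == 1) {
    return(list(list(g = states[1, ], p = 0.5),
                list(g = states[2, ], p = 0.5)))
  }
  rf <- arch$recomb_fraction
  out <- list()
  for (h in 1:2) for (sw in c(FALSE, TRUE)) {
    g <- c(states[h, 1], states[if (sw) 3 - h else h, 2])
    out[[length(out) + 1]] <- list(g = g,
                                   p = 0.5 * (if (sw) rf else 1 - rf))
  }
  out
}

oracle_deposition <- function(states, arch, params, active) {
  if (!active) return(list(list(st = states, p = 1)))
  slots <- which(states == "W", arr.ind = TRUE)
  res <- list(list(st = states, p = 1))
  if (nrow(slots) == 0) return(res)
  for (s in seq_len(nrow(slots))) {
    h <- slots[s, 1]; i <- slots[s, 2]
    d <- params$d[i]; rho <- params$rho
    branch <- list(list(x = "W", p = 1 - d),
                   list(x = "R", p = d * rho),
                   list(x = "B", p = d * (1 - rho)))
    nxt <- list()
    for (r in res) for (b in branch) {
      if (b$p == 0) next
      st2 <- r$st; st2[h, i] <- b$x
      nxt[[length(nxt) + 1]] <- list(st = st2, p = r$p * b$p)
    }
    res <- nxt
  }
  res
}

oracle_code <- function(states, sex, n) {
  if (is.matrix(states)) {
    h1 <- tgdrive:::hap_code(states[1, ], n)
    h2 <- if (any(states[2, ] == "Y")) "Y" else
      tgdrive:::hap_code(states[2, ], n)
  } else stop("states must be a matrix")
  tgdrive:::genotype_code(h1, h2, sex, n)
}

# full offspring distribution for one parental pair by brute force
oracle_offspring <- function(mother_code, father_code, arch, params) {
  n <- arch$n_loci
  parse <- function(code) {
    g <- tgdrive:::split_genotype(code)
    rbind(tgdrive:::hap_states(g$haps[1], n),
          if (g$haps[2] == "Y") rep("Y", n)
          else tgdrive:::hap_states(g$haps[2], n))
  }
  mst <- parse(mother_code); fst <- parse(father_code)
  xl <- arch$chromosome == "X"
  mother_active <- {
    cas9 <- sum(mst[, which(arch$roles != "grna_site"), drop = FALSE] == "T")
    grna <- sum(mst[, which(arch$roles != "cas9_site"), drop = FALSE] == "T")
    cas9 > 0 && grna > 0
  }
  acc <- new.env(); acc$p <- numeric(0)
  add <- function(code, p) {
    cur <- acc$p[code]
    acc$p[code] <- if (is.na(cur)) p else cur + p
  }
  for (mg in oracle_germline(mst, "F", arch, params)) {
    for (mgam in oracle_gametes(mg$st, arch)) {
      for (fg in oracle_germline(fst, "M", arch, params)) {
        for (fgam in oracle_gametes(fg$st, arch)) {
          p0 <- mg$p * mgam$p * fg$p * fgam$p
          if (p0 == 0) next
          if (identical(fgam$g, "Y")) {
            zyg <- rbind(mgam$g, rep("Y", n)); sexes <- "M"; sp <- 1
          } else if (xl) {
            zyg <- rbind(mgam$g, fgam$g); sexes <- "F"; sp <- 1
          } else {
            zyg <- rbind(mgam$g, fgam$g); sexes <- c("F", "M")
            sp <- 0.5
          }
          for (dz in oracle_deposition(zyg, arch, params, mother_active))
            for (sx in sexes)
              add(oracle_code(dz$st, sx, n), p0 * dz$p * sp)
        }
      }
    }
  }
  acc$p
}

# exhaustive randomization-test oracles -----------------------------------

oracle_perm_means <- function(a, b) {
  pooled <- c(a, b); na <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(pooled), na)
  ds <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  (1 + sum(abs(ds) >= abs(obs) - 1e-12)) / (ncol(idx) + 1)
}

oracle_perm_props <- function(sa, ta, sb, tb) {
  pooled <- c(rep(1, sa), rep(0, ta - sa), rep(1, sb), rep(0, tb - sb))
  obs <- sa / ta - sb / tb
  idx <- utils::combn(ta + tb, ta)
  ds <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  (1 + sum(abs(ds) >= abs(obs) - 1e-12)) / (ncol(idx) + 1)
}

# shared comparison: cube row vs oracle distribution
expect_cube_matches_oracle <- function(cube, mother, father, tol = 1e-12) {
  arch <- cube$architecture
  orc <- oracle_offspring(mother, father, arch, cube$params)
  row <- cube$tab[mother, father, ]
  row <- row[row > 0]
  expect_setequal(names(row), names(orc))
  orc <- orc[names(row)]
  expect_lt(max(abs(row - orc)), tol)
}
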