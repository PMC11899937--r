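# Independent oracles used by unit and acceptance tests. These deliberately
# take a different route than the package implementation.

# --- APOE diplotype oracle -------------------------------------------------
# Enumerate all 16 ordered pairs of the four two-site haplotypes, keep the
# pairs whose implied unphased genotypes match the observed ones, and read
# off the epsilon diplotypes. Returns the set of consistent diplotype labels
# partitioned into those inside the e2/e3/e4 system and those involving e1.
apoe_enumeration_oracle <- function(g429358, g7412) {
  haps <- list(e2 = c("T", "T"), e3 = c("T", "C"),
               e4 = c("C", "C"), e1 = c("C", "T"))
  unphased <- function(a, b) paste(sort(c(a, b)), collapse = "/")
  obs1 <- unphased(g429358[1], g429358[2])
  obs2 <- unphased(g7412[1], g7412[2])
  consistent <- character()
  for (h1 in names(haps)) {
    for (h2 in names(haps)) {
      ok1 <- unphased(haps[[h1]][1], haps[[h2]][1]) == obs1
      ok2 <- unphased(haps[[h1]][2], haps[[h2]][2]) == obs2
      if (ok1 && ok2) {
        consistent <- c(consistent, paste(sort(c(h1, h2)), collapse = ""))
      }
    }
  }
  consistent <- unique(consistent)
  list(
    valid = consistent[!grepl("e1", consistent)],
    with_e1 = consistent[grepl("e1", consistent)]
  )
}

# --- 2x2 Fisher oracle -----------------------------------------------------
# Literal brute force: enumerate every table with the observed margins,
# compute each table's probability from the factorial formula, and sum the
# probabilities of tables no more probable than the observed one.
fisher_brute_force <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- r1 + r2
  prob_of <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob_of, 0)
  p_obs <- prob_of(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# --- Kruskal-Wallis oracle -------------------------------------------------
# Direct evaluation of H = (12 / (N (N + 1))) * sum n_g rbar_g^2 - 3 (N + 1)
# divided by the tie-correction factor 1 - sum (t^3 - t) / (N^3 - N).
kruskal_brute_force <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# --- score-system brute force ----------------------------------------------
# All 3^5 dosage vectors crossed with all 6 diplotypes; returns every
# attainable score of the weight system.
all_scores_brute_force <- function(panel = ldl_panel()) {
  dosages <- expand.grid(rep(list(0:2), nrow(panel$snps)))
  snp_sums <- as.matrix(dosages) %*% panel$snps$weight
  as.vector(outer(drop(snp_sums), panel$apoe_weights$weight, `+`))
}
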