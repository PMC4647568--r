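# shared builders for the test suite

transitional_states <- c("transitional_two_vertebra", "transitional_single")

make_records <- function(n = 5, species = "testspecies", counts = 13L,
                         sacral = "regular", asym = NULL, zone = "central",
                         cervical = "regular") {
  sacral <- rep_len(sacral, n)
  if (is.null(asym)) {
    asym <- ifelse(sacral %in% transitional_states, "left", "none")
  }
  vertebral_records(
    specimen_id = sprintf("t%03d", seq_len(n)),
    species = rep_len(species, n),
    population_id = "pop1",
    zone = rep_len(zone, n),
    cervical_state = rep_len(cervical, n),
    thoracic_complete = rep_len(as.integer(counts), n),
    sacral_state = sacral,
    asymmetry = asym)
}

# random rooted binary tree with positive branch lengths, via ape
random_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# linear map from tip values to standardized contrasts (pic is linear)
contrast_matrix <- function(tree) {
  n <- length(tree$tip.label)
  vapply(seq_len(n), function(i) {
    x <- stats::setNames(as.numeric(seq_len(n) == i), tree$tip.label)
    pic_contrasts(tree, x)$contrast
  }, numeric(n - 1))
}

# Brownian tip draws via the tip covariance matrix (independent of
# simulate_bm): rows are replicates
bm_draws <- function(tree, nrep, sigma2 = 1, seed = 1) {
  set.seed(seed)
  C <- ape::vcv(tree)
  L <- chol(sigma2 * C)
  Z <- matrix(stats::rnorm(nrep * nrow(C)), nrep)
  X <- Z %*% L
  colnames(X) <- tree$tip.label
  X
}
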