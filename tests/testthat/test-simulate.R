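test_that("record simulation is seeded, reproducible and validated", {
  spec <- species_sim_spec("simsp", 40, 13,
                           count_spread = c("-1" = 0.2, "0" = 0.6, "1" = 0.2),
                           p_transitional = 0.1, p_cervical = 0.02)
  a <- simulate_records(spec, seed = 9)
  b <- simulate_records(spec, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_s3_class(a, "vertebral_records")
  expect_equal(nrow(a), 40)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_records(spec, seed = 10))))
  expect_named(attr(a, "seeds"), "simsp")
})

test_that("a degenerate spec yields identical regular records", {
  spec <- species_sim_spec("mono", 25, 14)
  rec <- simulate_records(spec, seed = 3)
  s <- summarize_species(rec, "mono")
  expect_equal(s$T_var, 0)
  expect_equal(s$S_tr, 0)
  expect_equal(s$T_range, 0)
  expect_true(all(rec$thoracic_complete == 14))
})

test_that("invalid spec probability mass is rejected", {
  expect_error(species_sim_spec("a", 10, 13, count_spread = c("0" = 0.5)),
               "sum to 1")
  expect_error(species_sim_spec("a", 10, 13, p_transitional = 1.2),
               "probability")
  expect_error(species_sim_spec("a", 0, 13), "positive")
})

test_that("sim specs round-trip through the CSV dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,n,modal_count,count_spread,p_transitional,p_cervical,zone",
               "alpha,50,13,-1:0.1;0:0.8;1:0.1,0.05,0.01,central",
               "beta,30,15,0:1,0,0,fringe"), f)
  specs <- read_sim_specs(f)
  expect_length(specs, 2)
  expect_equal(specs[[1]]$count_spread, c("-1" = 0.1, "0" = 0.8, "1" = 0.1))
  expect_equal(specs[[2]]$zone, "fringe")
  rec <- simulate_records(specs, seed = 1)
  expect_equal(nrow(rec), 80)
})

test_that("simulated samples recover the generating T_var and S_tr", {
  # specs mirror the published central-population rows: empirical integer
  # offsets and transitional rates; over 200 replicates the mean recovered
  # T_var should sit at the generating value
  # 100 * P(offset != 0) * (1 - p_transitional) up to Monte-Carlo error.
  # 16 mean comparisons are made at once, so per-species deviations are
  # judged at the 3.3-sigma familywise level and the pooled standardized
  # deviations additionally at a chi-square goodness-of-fit level.
  tab <- triturus_table1()
  species <- unique(tab$species)
  specs <- lapply(species, function(sp) {
    d <- tab[tab$species == sp, ]
    int <- d[d$score %% 1 == 0, ]
    modal <- int$score[which.max(int$count)]
    spread <- stats::setNames(int$count / sum(int$count),
                              as.integer(int$score - modal))
    species_sim_spec(sp, sum(d$count), modal, spread,
                     p_transitional = sum(d$count[d$score %% 1 != 0]) / sum(d$count))
  })
  names(specs) <- species
  q <- vapply(specs, function(s) 1 - s$count_spread[["0"]], numeric(1))
  ptr <- vapply(specs, `[[`, numeric(1), "p_transitional")
  expected <- 100 * q * (1 - ptr)

  reps <- 200
  tvar <- matrix(NA_real_, reps, length(species),
                 dimnames = list(NULL, species))
  str_ <- tvar
  for (r in seq_len(reps)) {
    s <- summary_table(simulate_records(specs, seed = 5000 + r))
    tvar[r, s$species] <- s$T_var
    str_[r, s$species] <- s$S_tr
  }
  z_tvar <- vapply(species, function(sp) {
    (mean(tvar[, sp]) - expected[[sp]]) / (sd(tvar[, sp]) / sqrt(reps))
  }, numeric(1))
  z_str <- vapply(species, function(sp) {
    (mean(str_[, sp]) - 100 * ptr[[sp]]) / (sd(str_[, sp]) / sqrt(reps))
  }, numeric(1))
  z <- c(z_tvar, z_str)
  expect_true(all(abs(z) < 3.3), label = "per-species mean deviations")
  expect_gt(stats::pchisq(sum(z^2), df = length(z), lower.tail = FALSE), 0.01)
})

test_that("Brownian tip values match closed-form moments", {
  tr <- read_newick("(A:2,B:3);")
  n <- 10000
  d <- vapply(seq_len(n), function(i) {
    x <- simulate_bm(tr, sigma2 = 1.3, root_state = 5, seed = i)
    x[["A"]] - x[["B"]]
  }, numeric(1))
  # Var(xA - xB) = sigma2 * (t1 + t2)
  v <- var(d)
  se <- v * sqrt(2 / n)
  expect_lt(abs(v - 1.3 * 5), 3 * se)
  expect_lt(abs(mean(d)), 3 * sqrt(1.3 * 5 / n))
  # degenerate limit: vanishing rate pins every tip at the root state
  x0 <- simulate_bm(tr, sigma2 = 1e-18, root_state = 5, seed = 1)
  expect_equal(unname(x0), c(5, 5), tolerance = 1e-6)
  expect_error(simulate_bm(tr, sigma2 = 0), "positive")
})

test_that("tip covariance equals rate times shared path length", {
  tr <- read_newick("((A:1,B:1):2,C:3);")
  n <- 10000
  X <- t(vapply(seq_len(n),
                function(i) simulate_bm(tr, sigma2 = 2, seed = 40000 + i),
                numeric(3)))
  emp <- cov(X)
  theo <- 2 * ape::vcv(tr)[colnames(X), colnames(X)]
  # 3-se bands on each covariance entry (normal-theory standard errors)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((theo[i, i] * theo[j, j] + theo[i, j]^2) / n)
    expect_lt(abs(emp[i, j] - theo[i, j]), 3 * se)
  }
})

test_that("mean squared standardized contrast estimates the Brownian rate", {
  tr <- triturus_tree()
  M <- contrast_matrix(tr)
  n <- 10000
  sq <- vapply(seq_len(n), function(i) {
    x <- simulate_bm(tr, sigma2 = 0.7, seed = 90000 + i)
    mean(drop(M %*% x[tr$tip.label])^2)
  }, numeric(1))
  est <- mean(sq)
  se <- sd(sq) / sqrt(n)
  expect_lt(abs(est - 0.7), 3 * se)
})

test_that("count-spread width coupled to the modal count drives the interspecific correlation", {
  ns <- c(58, 55, 175, 43, 66, 67, 122, 57)
  modal <- c(12, 12, 13, 13, 14, 14, 15, 17)
  sp_names <- paste0("sp", seq_along(ns))
  run_once <- function(qfun, rep) {
    specs <- lapply(seq_along(ns), function(i) {
      q <- qfun(modal[i])
      species_sim_spec(sp_names[i], ns[i], modal[i],
                       count_spread = c("-1" = q / 2, "0" = 1 - q, "1" = q / 2),
                       p_transitional = 0.05)
    })
    s <- summary_table(simulate_records(specs, seed = 7000 + rep))
    spearman_cor(s$T_n, s$T_var, permutations = 499, seed = rep)
  }
  reps <- 200
  strong <- vapply(seq_len(reps), function(r) {
    res <- run_once(function(m) 0.03 + 0.06 * (m - 12), r)
    res$p_perm < 0.05 && res$r_s > 0
  }, logical(1))
  expect_gte(mean(strong), 0.9)
  null_rej <- vapply(seq_len(reps), function(r) {
    run_once(function(m) 0.12, 1000 + r)$p_perm < 0.05
  }, logical(1))
  expect_gte(mean(null_rej), 0.005)
  expect_lte(mean(null_rej), 0.10)
})
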