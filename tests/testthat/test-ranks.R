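# Intensity ranking, the paired rank product with permutation pfp, and the
# cord/follow-up correlation analysis.

test_that("within-sample ranks average ties and ignore monotone transforms", {
  m <- cbind(s1 = c(10, 5, 1), s2 = c(10, 10, 1))
  rownames(m) <- c("a", "b", "c")
  r <- intensity_ranks(m)
  expect_equal(unname(r[, "s1"]), c(1, 2, 3))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  expect_equal(intensity_ranks(log2(m)), r)
  m[2, 1] <- NA
  expect_equal(unname(intensity_ranks(m)[, "s1"]), c(1, NA, 2))
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (rep in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    # missing values are excluded from the family, not imputed
    p_na <- c(p, NA)
    expect_equal(bh_adjust(p_na), c(oracle_bh(p), NA), tolerance = 1e-12)
  }
})

test_that("removing tail p-values never shrinks the BH discovery set", {
  set.seed(3)
  for (rep in 1:10) {
    p <- sort(runif(12))
    q_full <- bh_adjust(p)
    q_trim <- bh_adjust(p[1:8])
    # dropping the least significant members can only make the survivors
    # more significant, so discoveries at any threshold are preserved
    expect_true(all(q_trim <= q_full[1:8] + 1e-12))
  }
})

test_that("the rank product attains its minimum for a consistent winner", {
  cord <- rbind(a = c(9, 9), b = c(2, 3), c = c(3, 2), d = c(1, 1))
  colnames(cord) <- c("s1", "s2")
  fol <- matrix(2, 4, 2, dimnames = dimnames(cord))
  rp <- suppressWarnings(rank_product_test(cord, fol, B = 100, seed = 1))
  expect_equal(rp$rp_up[rp$protein_id == "a"], 1)  # ranked 1 in both pairs
  expect_equal(rp$direction[rp$protein_id == "a"], "up")
})

test_that("permutation pfp matches the exhaustive joint-enumeration oracle", {
  set.seed(9)
  for (m in 3:4) {
    for (k in 1:2) {
      cord <- matrix(rnorm(m * k), m, k,
                     dimnames = list(paste0("p", 1:m), paste0("s", 1:k)))
      fol <- matrix(rnorm(m * k), m, k, dimnames = dimnames(cord))
      d <- cord - fol
      ranks_up <- apply(d, 2, function(v) rank(-v))
      rp_obs <- exp(rowSums(log(matrix(ranks_up, m))) / k)
      expected <- oracle_rp_expected(rp_obs, m, k)
      pfp_oracle <- expected / rank(rp_obs, ties.method = "max")
      ord <- order(rp_obs)
      pfp_oracle[ord] <- rev(cummin(rev(pfp_oracle[ord])))

      # the in-package exact enumeration agrees with the joint oracle
      res <- rank_product_test(cord, fol, B = 10000, seed = 2)
      expect_equal(attr(res, "method"), "exact")
      expect_equal(res$pfp_up, pfp_oracle, tolerance = 1e-10)

      # the permutation estimate agrees within Monte-Carlo error at B = 1e4
      res_perm <- rank_product_test(cord, fol, B = 10000, seed = 2,
                                    max_exact = 1)
      expect_equal(attr(res_perm, "method"), "permutation")
      expect_equal(res_perm$pfp_up, pfp_oracle, tolerance = 0.15)
    }
  }
})

test_that("rank product results are equivariant under protein relabelling", {
  set.seed(12)
  cord <- matrix(rnorm(18), 6, 3,
                 dimnames = list(paste0("p", 1:6), paste0("s", 1:3)))
  fol <- matrix(rnorm(18), 6, 3, dimnames = dimnames(cord))
  res <- rank_product_test(cord, fol, B = 500, seed = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  res_perm <- rank_product_test(cord[perm, ], fol[perm, ], B = 500, seed = 3)
  reord <- match(res$protein_id, res_perm$protein_id)
  expect_equal(res_perm$rp_up[reord], res$rp_up)
  expect_equal(res_perm$pfp_up[reord], res$pfp_up)
})

test_that("pfp is monotone in rank-product order and warnings fire", {
  set.seed(4)
  cord <- matrix(rnorm(40), 10, 4,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  fol <- matrix(rnorm(40), 10, 4, dimnames = dimnames(cord))
  res <- rank_product_test(cord, fol, B = 2000, seed = 5, max_exact = 1)
  ord <- order(res$rp_up)
  expect_true(!is.unsorted(res$pfp_up[ord]))
  ord <- order(res$rp_down)
  expect_true(!is.unsorted(res$pfp_down[ord]))

  # unpaired subjects and low B warn
  cord2 <- cord
  colnames(cord2)[4] <- "s9"
  expect_warning(rank_product_test(cord2, fol, B = 2000, seed = 1,
                                   max_exact = 1), "unpaired")
  expect_warning(rank_product_test(cord, fol, B = 500, seed = 1,
                                   max_exact = 1), "permutations is low")
})

test_that("cord/follow-up Spearman correlations match first principles", {
  set.seed(6)
  subjects <- paste0("S", 1:6)
  cord <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("pa", "pb"), subjects))
  # pa follows cord perfectly at bin 3; pb is reversed
  fol3 <- rbind(pa = cord["pa", ] * 2 + 1, pb = -cord["pb", ])
  colnames(fol3) <- subjects
  res <- cord_followup_correlation(cord, list("3" = fol3), min_subjects = 5)
  expect_equal(res$rho[res$protein_id == "pa"], 1)
  expect_equal(res$rho[res$protein_id == "pb"], -1)
  expect_true(all(res$q >= res$p, na.rm = TRUE))

  # n = 5 arbitrary instance against the rank-covariance definition
  x <- c(2.3, -1, 0.5, 4, 1.1)
  y <- c(0.3, 2, -0.7, 1.5, 0.9)
  cord5 <- matrix(x, 1, 5, dimnames = list("pp", paste0("T", 1:5)))
  fol5 <- matrix(y, 1, 5, dimnames = list("pp", paste0("T", 1:5)))
  res5 <- cord_followup_correlation(cord5, list("3" = fol5))
  expect_equal(res5$rho, oracle_spearman(x, y), tolerance = 1e-12)

  # constant vectors yield missing rho
  folc <- matrix(1, 1, 5, dimnames = list("pp", paste0("T", 1:5)))
  resc <- cord_followup_correlation(cord5, list("3" = folc))
  expect_true(is.na(resc$rho))
})

test_that("Spearman rho ignores strictly monotone transforms", {
  set.seed(31)
  x <- rnorm(8); y <- rnorm(8)
  base <- oracle_spearman(x, y)
  cordm <- matrix(exp(x), 1, 8, dimnames = list("pp", paste0("T", 1:8)))
  folm <- matrix(y^3 + y, 1, 8, dimnames = list("pp", paste0("T", 1:8)))
  res <- cord_followup_correlation(cordm, list("3" = folm))
  expect_equal(res$rho, base, tolerance = 1e-12)
})
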