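# Contact detection and bootstrap contact-frequency estimation.

two_residue_model <- function(d) {
  toy_model(list(
    list(resid = 1L, chain = "A", resname = "ALA",
         atoms = list(CA = c(0, 0, 0), CB = c(1, 0, 0))),
    list(resid = 5L, chain = "A", resname = "ALA",
         atoms = list(CA = c(1 + d, 0, 0), CB = c(10, 10, 10)))))
}

test_that("the distance cutoff is inclusive and the diagonal excluded", {
  hit <- frame_contacts(two_residue_model(4.5), 1, cutoff = 4.5)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$res_i, hit$res_j), c(1L, 5L))
  miss <- frame_contacts(two_residue_model(4.5 + 1e-6), 1, cutoff = 4.5)
  expect_equal(nrow(miss), 0L)
  # a residue never contacts itself even when groups overlap
  both <- frame_contacts(two_residue_model(2), 1, cutoff = 100,
                         groupA = selection_spec(), groupB = selection_spec())
  expect_false(any(both$res_i == both$res_j & both$chain_i == both$chain_j))
})

test_that("frame range and cutoff preconditions are enforced", {
  m <- two_residue_model(2)
  expect_error(frame_contacts(m, 2, 4.5), regexp = "out of range")
  expect_error(frame_contacts(m, 1, 0), regexp = "cutoff")
})

test_that("contact sets match the brute-force all-atom-pair oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30L
    residues <- lapply(seq_len(n), function(i) {
      ctr <- runif(3, 0, 18)
      list(resid = i, chain = "A", resname = "ALA",
           atoms = list(CA = ctr, CB = ctr + runif(3, -1, 1),
                        O = ctr + runif(3, -1, 1)))
    })
    model <- toy_model(residues)
    got <- frame_contacts(model, 1, 4.5)
    got_key <- sort(paste(paste("A", got$res_i, sep = ":"),
                          paste("A", got$res_j, sep = ":")))
    expect_identical(got_key, brute_contacts(model, 1, 4.5))
  }
})

test_that("per-pair frequency is monotone non-decreasing in the cutoff", {
  set.seed(11)
  spec <- quick_spec(frames_per_trajectory = 20L)
  m <- generate_condition(spec, "A")
  plan <- bootstrap_plan(1L, 20L, with_replacement = FALSE)
  cuts <- c(3.5, 4.5, 6)
  freqs <- lapply(cuts, function(ct)
    bootstrap_frequencies(m, plan, ct, selection_spec(chain = "R"))$pairs$freq)
  expect_true(all(freqs[[1]] <= freqs[[2]]))
  expect_true(all(freqs[[2]] <= freqs[[3]]))
})

test_that("a degenerate ensemble gives frequency 1 with zero spread", {
  m1 <- two_residue_model(2)
  m <- structure_model(m1$atoms, m1$xyz[rep(1, 30), ], condition = "const")
  cf <- bootstrap_frequencies(m, bootstrap_plan(5L, 10L, seed = 3L), 4.5)
  i <- which(cf$pairs$res_i == 1L & cf$pairs$res_j == 5L)
  expect_equal(cf$pairs$freq[i], 1)
  expect_equal(cf$pairs$sd[i], 0)
})

test_that("an exhaustive no-replacement plan reduces to the plain frequency", {
  spec <- quick_spec(frames_per_trajectory = 40L)
  m <- generate_condition(spec, "A")
  plan <- bootstrap_plan(1L, 40L, with_replacement = FALSE)
  cf <- bootstrap_frequencies(m, plan, 4.5, selection_spec(chain = "R"))
  # independent per-frame scan for a handful of pairs
  idx <- c(1L, 50L, 200L, nrow(cf$pairs))
  for (k in idx) {
    ri <- cf$pairs$res_i[k]; rj <- cf$pairs$res_j[k]
    ai <- which(m$atoms$resid == ri & toupper(m$atoms$element) != "H")
    aj <- which(m$atoms$resid == rj & toupper(m$atoms$element) != "H")
    hits <- vapply(seq_len(n_frames(m)), function(f) {
      co <- matrix(m$xyz[f, ], ncol = 3, byrow = TRUE)
      any(as.vector(outer(ai, aj, Vectorize(function(x, y)
        sqrt(sum((co[x, ] - co[y, ])^2))))) <= 4.5)
    }, logical(1))
    expect_equal(cf$pairs$freq[k], mean(hits))
  }
  # all samples identical when drawing everything without replacement
  cf2 <- bootstrap_frequencies(m, bootstrap_plan(4L, 40L, FALSE, seed = 2L),
                               4.5, selection_spec(chain = "R"))
  expect_equal(max(cf2$pairs$sd), 0)
})

test_that("difference maps do the arithmetic, flagging and antisymmetry", {
  spec <- quick_spec(frames_per_trajectory = 30L)
  m <- generate_condition(spec, "A")
  plan <- bootstrap_plan(2L, 20L, seed = 4L)
  cf1 <- bootstrap_frequencies(m, plan, 4.5, selection_spec(chain = "R"))
  cf2 <- cf1
  cf2$pairs$freq <- pmin(1, cf1$pairs$freq + 0.15 * (cf1$pairs$freq > 0.2))
  dm <- difference_map(cf1, cf2, threshold = 0.10)
  expect_equal(dm$pairs$delta, cf2$pairs$freq - cf1$pairs$freq)
  expect_identical(dm$pairs$flagged, abs(dm$pairs$delta) >= 0.10)
  expect_identical(dm$pairs$both_conditions,
                   cf1$pairs$freq > 0 & cf2$pairs$freq > 0)
  # identity: nothing flagged
  d0 <- difference_map(cf1, cf1, 0.10)
  expect_true(all(d0$pairs$delta == 0))
  expect_false(any(d0$pairs$flagged))
  # antisymmetry under argument swap
  rev <- difference_map(cf2, cf1, 0.10)
  expect_equal(rev$pairs$delta, -dm$pairs$delta)
  # cutoff mismatch is an error
  cf3 <- bootstrap_frequencies(m, plan, 5.0, selection_spec(chain = "R"))
  expect_error(difference_map(cf1, cf3), regexp = "cutoff")
})

test_that("interface contacts are the same operation across chains", {
  spec <- quick_spec(frames_per_trajectory = 30L)
  m <- generate_condition(spec, "A")
  plan <- bootstrap_plan(2L, 30L, seed = 6L)
  cf <- bootstrap_frequencies(m, plan, 4.5,
                              selection_spec(chain = "R"),
                              selection_spec(chain = "G"))
  expect_true(all(cf$pairs$chain_i == "R" & cf$pairs$chain_j == "G"))
  truth <- attr(m, "truth")$plants
  iface <- truth[truth$chain_j == "G", ]
  for (k in seq_len(nrow(iface))) {
    i <- which(cf$pairs$res_i == iface$res_i[k] & cf$pairs$res_j == iface$res_j[k])
    expect_gt(cf$pairs$freq[i], 0)
  }
})
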