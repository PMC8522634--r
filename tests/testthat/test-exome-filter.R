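site <- function(ref, counts, contig = "c1", pos = 100L) {
  m <- as.list(c(A = 0L, C = 0L, G = 0L, T = 0L))
  m[names(counts)] <- as.integer(counts)
  cbind(data.frame(contig = contig, pos = pos, ref = ref),
        as.data.frame(m))
}

test_that("the >=3-read calling rule calls the 34/564 exome candidate and
           nothing below it", {
  s <- site("A", c(A = 530, G = 34))
  v <- call_candidate_sites(s)
  expect_equal(nrow(v), 1L)
  expect_equal(v$alt, "G")
  expect_equal(v$alt_count, 34L)
  expect_equal(v$depth, 564L)
  expect_equal(round_percent(v$alt_count, v$depth, 0), 6)

  expect_equal(nrow(call_candidate_sites(site("A", c(A = 500, G = 2)))), 0L)
  # exactly at the rule boundary
  expect_equal(nrow(call_candidate_sites(site("A", c(A = 500, G = 3)))), 1L)
})

test_that("a site can emit several variants, matching a per-base threshold
           enumeration", {
  s <- site("A", c(A = 100, G = 3, T = 3, C = 2))
  v <- call_candidate_sites(s)
  expect_setequal(v$alt, c("G", "T"))
  # enumerate all base tallies against the threshold directly
  set.seed(5)
  for (i in 1:50) {
    cc <- sample(0:6, 4, TRUE)
    names(cc) <- c("A", "C", "G", "T")
    s2 <- site("A", cc)
    v2 <- call_candidate_sites(s2)
    expect_setequal(v2$alt,
                    setdiff(names(cc)[cc >= 3], "A"))
  }
})

test_that("affected filters honor both boundary semantics exactly", {
  mk <- function(alt_count, pop_af, cons)
    data.frame(contig = "c1", pos = 1L, ref = "A", alt = "G",
               alt_count = alt_count, depth = 500L, pop_af = pop_af,
               conservation_score = cons, gene = "g", effect = "ms")
  # alt_count "at least 15" is inclusive; AF "below 1%" and score "above 5"
  # are strict
  expect_equal(nrow(filter_affected(mk(15, 0, 5.01))), 1L)
  expect_equal(nrow(filter_affected(mk(14, 0, 8))), 0L)
  expect_equal(nrow(filter_affected(mk(34, 0, 5.5))), 1L)
  expect_equal(nrow(filter_affected(mk(20, 0.01, 8))), 0L)   # not < 1%
  expect_equal(nrow(filter_affected(mk(20, 0.0099, 8))), 1L)
  expect_equal(nrow(filter_affected(mk(20, 0, 5))), 0L)      # not > 5
  # missing AF passes (novel variant), missing conservation fails
  expect_equal(nrow(filter_affected(mk(20, NA, 8))), 1L)
  expect_equal(nrow(filter_affected(mk(20, 0, NA))), 0L)
})

test_that("affected filters match a row-wise brute-force predicate on 1000
           simulated variants", {
  set.seed(7)
  n <- 1000
  v <- data.frame(contig = "c1", pos = seq_len(n), ref = "A", alt = "G",
                  alt_count = sample(0:60, n, TRUE), depth = 500L,
                  pop_af = ifelse(runif(n) < 0.1, NA, runif(n, 0, 0.05)),
                  conservation_score = ifelse(runif(n) < 0.1, NA,
                                              runif(n, -2, 8)),
                  gene = "g", effect = "ms")
  got <- filter_affected(v)
  keep <- vapply(seq_len(n), function(i) {
    af <- if (is.na(v$pop_af[i])) 0 else v$pop_af[i]
    v$alt_count[i] >= 15 && af < 0.01 &&
      (!is.na(v$conservation_score[i]) && v$conservation_score[i] > 5)
  }, logical(1))
  expect_equal(got$pos, v$pos[keep])
  expect_equal(sum(attr(got, "removed")), sum(!keep))
})

test_that("unaffected subtraction is strict at 'over 5' and preserves
           order", {
  aff <- data.frame(contig = "c1", pos = c(1L, 2L, 3L), ref = "A",
                    alt = "G", alt_count = 30L, depth = 500L,
                    pop_af = 0, conservation_score = 8, gene = "g",
                    effect = "ms")
  unaff <- data.frame(contig = "c1", pos = c(1L, 2L, 3L), ref = "A",
                      alt = "G", alt_count = c(0L, 5L, 6L), depth = 400L,
                      pop_af = 0, conservation_score = 8, gene = "g",
                      effect = "ms")
  got <- subtract_unaffected(aff, unaff)
  expect_equal(got$pos, c(1L, 2L))  # 0 kept, 5 kept (not over 5), 6 removed
  expect_equal(attr(got, "removed")[["shared_with_unaffected"]], 1L)
  expect_error(subtract_unaffected(rbind(aff, aff[1, ]), unaff),
               "duplicate")
})

test_that("subtraction equals a keyed set-difference oracle on random
           paired tables", {
  set.seed(13)
  for (i in 1:20) {
    n <- 50
    pos_a <- sample(1:200, n)
    aff <- data.frame(contig = "c1", pos = pos_a, ref = "A", alt = "G",
                      alt_count = sample(15:40, n, TRUE), depth = 500L,
                      pop_af = 0, conservation_score = 8, gene = "g",
                      effect = "ms")
    pos_u <- sample(1:200, n)
    unaff <- data.frame(contig = "c1", pos = pos_u, ref = "A", alt = "G",
                        alt_count = sample(0:12, n, TRUE), depth = 400L,
                        pop_af = 0, conservation_score = 8, gene = "g",
                        effect = "ms")
    got <- subtract_unaffected(aff, unaff)
    bad_keys <- unaff$pos[unaff$alt_count > 5]
    expect_equal(got$pos, aff$pos[!(aff$pos %in% bad_keys)])
  }
})

test_that("the full cascade recovers exactly the planted survivors and
           reports stage tallies", {
  sim <- simulate_variant_table(500, seed = 21)
  res <- run_cascade(sim$affected_sites, sim$unaffected_sites,
                     sim$annotations)
  truth_keys <- with(sim$truth[sim$truth$survives, ],
                     paste(contig, pos, alt))
  got_keys <- with(res$candidates, paste(contig, pos, alt))
  expect_setequal(got_keys, truth_keys)
  expect_equal(res$tallies[["after_unaffected_subtraction"]],
               nrow(res$candidates))
  # empty input
  empty <- run_cascade(site("A", c(A = 1))[0, ], site("A", c(A = 1))[0, ],
                       data.frame(contig = character(0), pos = integer(0),
                                  alt = character(0), pop_af = numeric(0),
                                  conservation_score = numeric(0)))
  expect_equal(nrow(empty$candidates), 0L)
  expect_equal(empty$tallies[["called_affected"]], 0L)
})

test_that("tightening any threshold never increases the survivor count", {
  sim <- simulate_variant_table(400, seed = 3)
  base_cfg <- filter_config()
  base_n <- nrow(run_cascade(sim$affected_sites, sim$unaffected_sites,
                             sim$annotations, base_cfg)$candidates)
  set.seed(9)
  for (i in 1:100) {
    cfg <- filter_config(
      call_min_alt = sample(3:10, 1),
      affected_min_alt = sample(15:40, 1),
      max_pop_af = runif(1, 0, 0.01),
      min_conservation = runif(1, 5, 7),
      unaffected_subtract_min_alt = sample(0:5, 1))
    n <- nrow(run_cascade(sim$affected_sites, sim$unaffected_sites,
                          sim$annotations, cfg)$candidates)
    expect_lte(n, base_n)
  }
})
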