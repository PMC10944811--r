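test_that("informative sites are exactly the parent-discriminating positions", {
  ref <- "ACGTACGTACGT"
  expect_equal(nrow(informative_sites(ref, ref, ref)), 0L)

  # 12-mers differing at offsets 3, 7, 11; query matches the donor at 7 only
  donor <- substitute_at(ref, c(3L, 7L, 11L), c("T", "C", "A"))
  query <- substitute_at(ref, 7L, "C")
  sites <- informative_sites(query, ref, donor)
  expect_equal(sites$position, c(3L, 7L, 11L))
  expect_equal(sites$state, c("matches_ref", "matches_donor", "matches_ref"))

  # a query base matching neither parent is a residual candidate
  query2 <- substitute_at(query, 11L, "C")  # ref G, donor A there
  sites2 <- informative_sites(query2, ref, donor)
  expect_equal(sites2$state[3L], "matches_neither")

  # unknown / ambiguous positions in a parent are excluded
  donor_n <- substitute_at(donor, 3L, "N")
  expect_equal(informative_sites(query, ref, donor_n)$position, c(7L, 11L))

  expect_error(informative_sites("ACGT", ref, donor), "equal")
})

test_that("segmentation is the minimal-switch path over matched sites", {
  # D..D R..R D..D is a double crossover with two breakpoint intervals
  rep <- segment_parental_path(sites_from_states(c("D", "D", "R", "R", "R",
                                                   "D", "D")))
  expect_equal(rep$n_switches, 2L)
  expect_equal(rep$segments$source, c("donor", "reference", "donor"))
  expect_equal(rep$breakpoint_intervals$lower, c(20L, 50L))
  expect_equal(rep$breakpoint_intervals$upper, c(30L, 60L))

  rep2 <- segment_parental_path(sites_from_states(rep("R", 5L)))
  expect_equal(rep2$n_switches, 0L)
  expect_equal(render_breakpoints(rep2), "no recombination")

  expect_error(segment_parental_path(sites_from_states(c("N", "N"))), "no call")
  expect_error(segment_parental_path(sites_from_states(character(0L))))

  # matches_neither sites are set aside as residuals, not segmented
  rep3 <- segment_parental_path(sites_from_states(c("R", "N", "R", "D", "D")))
  expect_equal(rep3$residual_positions, 20L)
  expect_equal(rep3$n_switches, 1L)
})

test_that("reported switches equal the DP and enumeration oracles", {
  set.seed(17)
  # exhaustive over every two-state pattern up to length 10
  for (k in 1:10) {
    for (code in 0:(2^k - 1L)) {
      states <- ifelse(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L, "D", "R")
      rep <- segment_parental_path(sites_from_states(states))
      expect_equal(rep$n_switches, oracle_min_switches(states))
    }
  }
  # spot-check the DP oracle itself against full enumeration
  for (i in 1:50) {
    states <- sample(c("R", "D"), sample(2:8, 1L), replace = TRUE)
    expect_equal(oracle_min_switches(states),
                 oracle_min_switches_enum(states))
  }
})

test_that("true breakpoints of synthetic recombinants lie inside reported intervals", {
  set.seed(29)
  n <- 1500L
  for (rep_i in 1:30) {
    root <- random_seq(n)
    # informative scaffold roughly every 50 nt
    scaffold <- seq(25L, n - 25L, by = 50L) + sample(-10:10, 30L, replace = TRUE)
    donor <- root
    for (p in scaffold) donor <- flip_base(donor, p)
    bps <- c(sample(100:700, 1L), sample(800:1400, 1L))
    rec <- make_recombinant(root, donor, bps)
    report <- segment_parental_path(informative_sites(rec$sequence, root, donor))
    expect_equal(report$n_switches, 2L)
    bp <- report$breakpoint_intervals
    expect_true(all(bp$lower <= bps & bps < bp$upper))
  }
})

test_that("reports are invariant to padding both flanks", {
  set.seed(37)
  root <- random_seq(400)
  donor <- root
  for (p in seq(20L, 380L, by = 40L)) donor <- flip_base(donor, p)
  query <- make_recombinant(root, donor, c(150L, 250L))$sequence
  base_rep <- segment_parental_path(informative_sites(query, root, donor))
  pad <- random_seq(50)
  padded <- function(s) paste0(pad, s, pad)
  pad_rep <- segment_parental_path(
    informative_sites(padded(query), padded(root), padded(donor),
                      positions = c(-(50:1), 1:400, 401:450))
  )
  # positions of the core coordinates are unchanged
  expect_equal(pad_rep$segments, base_rep$segments)
  expect_equal(pad_rep$breakpoint_intervals, base_rep$breakpoint_intervals)
})

test_that("donor scan calls conversions only on multi-site evidence", {
  set.seed(41)
  n <- 1200L
  root <- random_seq(n)
  # query identical to the reference: no call for any donor
  panel <- stats::setNames(lapply(1:5, function(i) mutate_sequence(root, 0.02)),
                           sprintf("B*%02d:01", 10 + 1:5))
  panel <- vapply(panel, identity, character(1L))
  scan <- scan_donor_panel(root, root, panel)
  expect_false(scan$called)

  # isolated point mutations only: segments below min_sites_per_segment
  query_pm <- flip_base(flip_base(root, 300L), 900L)
  scan_pm <- scan_donor_panel(query_pm, root, panel)
  expect_false(scan_pm$called)

  # a true double-crossover donor is called and ranked first in >= 95% of
  # replicates (an exchanged tract can by chance carry too few informative
  # sites for the multi-site support rule, which then correctly stays silent)
  hits <- 0L
  n_rep <- 40L
  root2 <- random_seq(1500L)
  for (i in seq_len(n_rep)) {
    panel_i <- vapply(1:20, function(j) mutate_sequence(root2, 0.02),
                      character(1L))
    names(panel_i) <- sprintf("B*%02d:01", 20 + 1:20)
    true_donor <- sample(names(panel_i), 1L)
    query <- make_recombinant(root2, panel_i[[true_donor]],
                              c(400L, 1000L))$sequence
    scan_i <- scan_donor_panel(query, root2, panel_i)
    if (scan_i$called && true_donor %in% scan_i$best) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
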