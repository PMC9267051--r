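test_that("odds scores reproduce the published superfamily table cells", {
  counts <- superfamily_counts()
  scores <- odds_score(counts, ps = 5) |>
    dplyr::mutate(score2 = round_half_away(score, 2))

  expected <- published_odds_scores() |>
    tidyr::pivot_longer(-signature_id, names_to = "genus",
                        values_to = "expected")
  joined <- dplyr::left_join(scores, expected, by = c("genus", "signature_id"))
  expect_equal(nrow(joined), 128L)
  expect_equal(joined$score2, joined$expected)
})

test_that("identical counts across genera score zero everywhere", {
  flat <- tibble::tibble(genus = c("A", "B", "C"), signature_id = "S1", n = 12L)
  expect_equal(odds_score(flat, ps = 5)$score, rep(0, 3))
})

test_that("odds scores match a direct per-cell evaluation on random matrices", {
  withr::with_seed(21, {
    m <- matrix(rpois(50, 30), nrow = 5,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:10)))
  })
  got <- odds_score(m, ps = 5)
  wide <- tibble::as_tibble(t(m), rownames = "signature_id")
  oracle <- oracle_odds(wide, ps = 5)
  joined <- dplyr::left_join(got, oracle, by = c("genus", "signature_id"),
                             suffix = c("", "_oracle"))
  expect_equal(joined$score, joined$score_oracle)
})

test_that("odds score guards degenerate inputs", {
  one_genus <- tibble::tibble(genus = "A", signature_id = c("S1", "S2"),
                              n = c(1L, 2L))
  expect_error(odds_score(one_genus), "2 genera")
  zeros <- tibble::tibble(genus = c("A", "B"), signature_id = "S1", n = c(0L, 3L))
  expect_error(odds_score(zeros, ps = 0), "ps > 0")
  # ps = 0 is fine when counts are all positive
  pos <- tibble::tibble(genus = c("A", "B"), signature_id = "S1", n = c(2L, 6L))
  expect_equal(odds_score(pos, ps = 0)$score, log2(c(2, 6) / 4))
})

test_that("odds score is monotone in the focal count and brackets zero", {
  # monotonicity: growing one cell strictly increases its score
  base <- tibble::tibble(genus = c("A", "B", "C"), signature_id = "S1",
                         n = c(10L, 20L, 30L))
  s0 <- odds_score(base, ps = 5)$score[1]
  grown <- base; grown$n[1] <- 11L
  expect_gt(odds_score(grown, ps = 5)$score[1], s0)

  # for each signature, at least one genus >= 0 and at least one <= 0
  for (seed in 1:10) {
    sim <- simulate_annotations(paste0("G", 1:4), n_signatures = 8,
                                base_rate = 20, seed = seed)
    sc <- odds_score(sim$truth, ps = 5)
    by_sig <- split(sc$score, sc$signature_id)
    for (s in by_sig) {
      expect_gte(max(s), 0)
      expect_lte(min(s), 0)
    }
  }
})

test_that("odds scores and rankings are invariant to input row order", {
  counts <- superfamily_counts()
  shuffled <- withr::with_seed(4, counts[sample.int(nrow(counts)), ])
  a <- odds_score(counts, ps = 5)
  b <- odds_score(shuffled, ps = 5)
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), genus, signature_id)$score
  expect_equal(key(a), key(b))
  expect_equal(rank_odds(a, "Tco")$highest$signature_id,
               rank_odds(b, "Tco")$highest$signature_id)
})

test_that("ranking orders signatures by the focal genus's score", {
  counts <- superfamily_counts()
  r <- odds_score(dplyr::select(counts, genus, signature_id, n), ps = 5)
  cats <- dplyr::distinct(counts, signature_id, category)
  rk <- rank_odds(r, "Tco", categories = cats)
  metab <- dplyr::filter(rk$highest, category == "Metabolism")
  # published ordering of the Tco metabolism scores
  expect_equal(round_half_away(metab$score[1:6], 2),
               c(2.36, 1.86, 1.60, 1.48, 1.38, 0.90))
  expect_equal(rk$lowest$signature_id[1], "IPR039512")
  expect_error(rank_odds(r, "nope"), "unknown genus")

  single <- odds_score(tibble::tibble(genus = c("A", "B"),
                                      signature_id = "S1", n = c(4L, 8L)))
  one <- rank_odds(single, "A")
  expect_equal(one$highest$signature_id, "S1")
  expect_equal(one$lowest$signature_id, "S1")
})

test_that("count matrices deduplicate genes and complete missing cells", {
  ann <- tibble::tibble(
    genus = c("A", "A", "A", "B"),
    gene_id = c("a1", "a1", "a2", "b1"),
    signature_id = c("IPR036396", "IPR036396", "IPR036041", "IPR035992")
  )
  cm <- build_count_matrix(ann)
  get <- function(g, s) cm$n[cm$genus == g & cm$signature_id == s]
  expect_equal(get("A", "IPR036396"), 1L)  # two hits of one signature: one gene
  expect_equal(get("A", "IPR036041"), 1L)
  expect_equal(get("B", "IPR036396"), 0L)  # completed cell
  expect_equal(nrow(cm), 6L)

  # a gene with two different signatures counts once under each
  multi <- tibble::tibble(genus = c("A", "A", "B"),
                          gene_id = c("a1", "a1", "b1"),
                          signature_id = c("S1", "S2", "S1"))
  cm2 <- build_count_matrix(multi)
  expect_equal(cm2$n[cm2$genus == "A"], c(1L, 1L))

  expect_error(build_count_matrix(ann[ann$genus == "A", ]), "2 genera")
})

test_that("simulated annotation sets yield their planted count matrix", {
  sim <- simulate_annotations(c("Tco", "Tci", "Cs"), n_signatures = 12,
                              base_rate = 25,
                              expansions = tibble::tibble(
                                genus = "Tco", signature_id = "SF0003",
                                fold = 4),
                              seed = 13)
  cm <- build_count_matrix(sim$annotations)
  joined <- dplyr::left_join(sim$truth, cm, by = c("genus", "signature_id"),
                             suffix = c("_truth", "_got"))
  expect_equal(joined$n_got, joined$n_truth)

  # duplicate-hit noise on or off leaves the truth matrix unchanged
  sim_nodup <- simulate_annotations(c("Tco", "Tci", "Cs"), n_signatures = 12,
                                    base_rate = 25,
                                    expansions = tibble::tibble(
                                      genus = "Tco", signature_id = "SF0003",
                                      fold = 4),
                                    dup_noise = 0, seed = 13)
  expect_equal(sim$truth, sim_nodup$truth)
  expect_equal(as.data.frame(build_count_matrix(sim_nodup$annotations)),
               as.data.frame(cm))
})
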