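rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

test_that("probe tiling is left-greedy, gapped and reverse-complementary", {
  p1 <- tile_probes(strrep("ACGT", 5))   # exactly 20 nt
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$start, 0L)
  expect_equal(p1$sequence, oracle_revcomp(strrep("ACGT", 5)))

  # 42 nt fits two probes: 20 + 2 gap + 20
  withr::with_seed(3, {
    t42 <- rand_dna(42)
    p42 <- tile_probes(t42)
    expect_equal(p42$start, c(0L, 22L))
    expect_equal(p42$sequence[2], oracle_revcomp(substr(t42, 23, 42)))
  })
  # 41 nt does not
  withr::with_seed(3, expect_equal(nrow(tile_probes(rand_dna(41))), 1L))

  expect_warning(p0 <- tile_probes("ACGTACGT"), "shorter")
  expect_equal(nrow(p0), 0L)
})

test_that("greedy tiling count is maximal for all short targets", {
  withr::with_seed(33, {
    for (L in c(20, 43, 44, 65, 66, 87, 100)) {
      p <- tile_probes(rand_dna(L), max_probes = 1000L)
      # maximal non-overlapping placement with gap >= 2: floor((L+2)/22)
      expect_equal(nrow(p), floor((L + 2) / 22))
      if (nrow(p) > 1) {
        expect_true(all(diff(p$start) >= 22))
      }
      expect_true(all(p$start + 20 <= L))
    }
  })
})

test_that("a 1.1 kb coding sequence yields a 43-48 oligo probe set", {
  withr::with_seed(35, {
    cds <- rand_dna(1050)  # study-like CDS length
    p <- tile_probes(cds)
    expect_gte(nrow(p), 43)
    expect_lte(nrow(p), 48)
  })
})

test_that("off-target filtering excludes close matches and keeps distant ones", {
  withr::with_seed(41, {
    target <- rand_dna(200)
    probes <- tile_probes(target)
    # transcript containing an exact copy of the first probe's target window
    hot <- paste0(rand_dna(50), probes$target_window[1], rand_dna(50))
    tx <- c(target = target, hot = hot, cold = rand_dna(150))
    res <- offtarget_filter(probes, tx, target_id = "target")
    expect_true("probe_01" %in% res$excluded$probe_id)
    expect_equal(res$excluded$best_mismatches[res$excluded$probe_id == "probe_01"], 0L)
    expect_equal(res$excluded$best_transcript[res$excluded$probe_id == "probe_01"], "hot")
    # a probe with >= 10 mismatches everywhere is kept
    kept_best <- res$kept$best_mismatches
    expect_true(all(kept_best > 3L))
  })
})

test_that("off-target decisions agree with the exhaustive Hamming oracle", {
  withr::with_seed(43, {
    tx <- c(t1 = rand_dna(400), t2 = rand_dna(300), t3 = rand_dna(300))
    probes <- tibble::tibble(
      probe_id = sprintf("p%02d", 1:15),
      sequence = vapply(1:15, function(i) rand_dna(20), character(1))
    )
    res <- offtarget_filter(probes, tx, target_id = character(0))
    all_res <- rbind(res$kept, res$excluded)
    all_res <- all_res[order(all_res$probe_id), ]
    for (i in seq_len(nrow(all_res))) {
      q <- all_res$sequence[i]
      want <- min(oracle_best_hamming(oracle_revcomp(q), unname(tx)),
                  oracle_best_hamming(q, unname(tx)))
      expect_equal(all_res$best_mismatches[i], want)
      expect_equal(all_res$excluded[i], want <= 3L)
    }
  })
})

test_that("off-target exclusion matches Biostrings max-mismatch counting", {
  withr::with_seed(47, {
    tx <- c(a = rand_dna(500), b = rand_dna(500))
    probes <- tibble::tibble(probe_id = sprintf("p%02d", 1:10),
                             sequence = vapply(1:10, function(i) rand_dna(20),
                                               character(1)))
    res <- offtarget_filter(probes, tx)
    all_res <- rbind(res$kept, res$excluded)
    subj <- Biostrings::DNAStringSet(unname(tx))
    for (i in seq_len(nrow(all_res))) {
      q <- all_res$sequence[i]
      hits <- sum(Biostrings::vcountPattern(
        Biostrings::DNAString(ramfish:::revcomp(q)), subj, max.mismatch = 3)) +
        sum(Biostrings::vcountPattern(Biostrings::DNAString(q), subj,
                                      max.mismatch = 3))
      expect_equal(all_res$excluded[all_res$sequence == q], hits > 0)
    }
  })
})

test_that("gene screening applies the four selection criteria", {
  withr::with_seed(53, {
    short_gene <- list(gene_id = "G1", isoforms = rand_dna(600))
    rep1 <- screen_gene(short_gene)
    expect_false(rep1$pass)
    expect_false(rep1$criteria$pass[rep1$criteria$criterion == "length_gt_700"])
    expect_gte(length(rep1$reasons), 1L)

    # polyA tail does not count toward length
    body <- rand_dna(690)
    tailed <- list(gene_id = "G2", isoforms = paste0(body, strrep("A", 30)))
    rep2 <- screen_gene(tailed)
    expect_false(rep2$criteria$pass[rep2$criteria$criterion == "length_gt_700"])

    good_seq <- rand_dna(1200)
    good <- list(gene_id = "G3", isoforms = good_seq)
    rep3 <- screen_gene(good)
    expect_true(rep3$pass)

    # a close homologue (2% divergence) breaks paralogue distinctness
    mutate_seq <- function(s, rate) {
      ch <- strsplit(s, NULL)[[1]]
      idx <- which(runif(length(ch)) < rate)
      ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      paste(ch, collapse = "")
    }
    homolog <- list(gene_id = "G3b", isoforms = mutate_seq(good_seq, 0.02))
    rep4 <- screen_gene(good, gene_family = list(homolog))
    expect_false(rep4$pass)
    expect_false(rep4$criteria$pass[rep4$criteria$criterion == "paralogue_distinct"])
    # an unrelated family member does not
    rep5 <- screen_gene(good, gene_family = list(
      list(gene_id = "G4", isoforms = rand_dna(1200))))
    expect_true(rep5$pass)

    # too many isoforms fail criterion (iii)
    many <- list(gene_id = "G5",
                 isoforms = c(good_seq, good_seq, good_seq, good_seq))
    rep6 <- screen_gene(many)
    expect_false(rep6$criteria$pass[rep6$criteria$criterion == "few_isoforms"])

    # two isoforms sharing a 1000-nt exon pass the common-coverage criterion
    exon <- rand_dna(1000)
    iso_gene <- list(gene_id = "G6",
                     isoforms = c(paste0(rand_dna(100), exon),
                                  paste0(exon, rand_dna(60))))
    rep7 <- screen_gene(iso_gene)
    expect_true(rep7$criteria$pass[rep7$criteria$criterion == "common_exon_coverage"])
    expect_gte(rep7$common_run_nt, 1000)

    # short shared region fails it
    iso_bad <- list(gene_id = "G7",
                    isoforms = c(paste0(rand_dna(400), rand_dna(400)),
                                 rand_dna(800)))
    rep8 <- screen_gene(iso_bad)
    expect_false(rep8$criteria$pass[rep8$criteria$criterion == "common_exon_coverage"])
  })
})

test_that("screening is order-independent in the gene family list", {
  withr::with_seed(59, {
    g <- list(gene_id = "X", isoforms = rand_dna(900))
    fam <- list(list(gene_id = "Y", isoforms = rand_dna(900)),
                list(gene_id = "Z", isoforms = rand_dna(700)))
    r1 <- screen_gene(g, fam)
    r2 <- screen_gene(g, rev(fam))
    expect_equal(r1$criteria$pass, r2$criteria$pass)
  })
})

test_that("malformed sequences are rejected", {
  expect_error(screen_gene(list(gene_id = "B", isoforms = "ACGU-XY")), "A,C,G,T")
  expect_error(tile_probes("ACGTXACGT"), "A,C,G,T")
})
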