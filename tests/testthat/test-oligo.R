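test_that("mixmer parsing recovers lengths, chemistry, labels and segments", {
  on2 <- parse_mixmer("5'-CcTtTtCtTtTtTcT-3'")
  expect_equal(nt_length(on2), 15)
  expect_equal(which(on2$chemistry == "LNA"), c(1, 3, 5, 7, 9, 11, 13, 15))

  on1 <- parse_mixmer("ccttttcttttttct")
  expect_equal(nt_length(on1), 15)
  expect_equal(count_lna(on1), 0)
  expect_equal(sum(on1$chemistry == "TINA"), 0)

  bis <- parse_mixmer("Cy3-CcTtTtCtTtTtTcT-tctct-tCtTtTtTcTtTtCcCccAcgCccTctGc")
  expect_equal(nt_length(bis), 49)
  expect_equal(attr(bis, "label5"), "Cy3")
  expect_equal(as.vector(table(bis$segment)), c(15L, 5L, 29L))

  tina <- parse_mixmer("C**P**cTtTtCtTtTtTcT")
  expect_equal(nt_length(tina), 15)
  expect_equal(sum(tina$chemistry == "TINA"), 1)
  expect_equal(which(tina$chemistry == "TINA"), 2)  # between nucleotides 1 and 2
  expect_true(is.na(tina$base[2]))

  # unicode primes and reversed (3'->5') notation both normalize
  rev_oligo <- parse_mixmer("3′-cGtcTccCgcAccCcCtTtTcTtTtTtCt-Cy5-5′")
  expect_equal(attr(rev_oligo, "label5"), "Cy5")
  expect_equal(substr(lnahelix:::oligo_bases(rev_oligo), 1, 3), "TCT")
})

test_that("parse errors identify the offending character and strict TINA mode works", {
  expect_error(parse_mixmer("ccXtt"), "unknown character 'X' at monomer position 3",
               class = "lnahelix_parse_error")
  expect_error(parse_mixmer("ccQtt"), class = "lnahelix_parse_error")
  expect_error(parse_mixmer("CPc", tina_strict = TRUE), class = "lnahelix_parse_error")
  expect_equal(sum(parse_mixmer("CPc")$chemistry == "TINA"), 1)
  expect_equal(sum(parse_mixmer("C**P**c", tina_strict = TRUE)$chemistry == "TINA"), 1)
})

test_that("every shipped oligo reproduces its printed length and round-trips", {
  tab <- paper_oligos()
  for (i in seq_len(nrow(tab))) {
    o <- parse_mixmer(tab$notation[i], name = tab$name[i])
    expect_equal(nt_length(o), tab$length[i], info = tab$name[i])
    # parse -> serialize -> parse identity on bases, chemistry, labels, segments
    o2 <- parse_mixmer(format_mixmer(o))
    expect_equal(o2$base, o$base, info = tab$name[i])
    expect_equal(o2$chemistry, o$chemistry, info = tab$name[i])
    expect_equal(o2$segment, o$segment, info = tab$name[i])
    expect_equal(attr(o2, "label5"), attr(o, "label5"), info = tab$name[i])
    expect_equal(attr(o2, "label3"), attr(o, "label3"), info = tab$name[i])
  }
})

test_that("LNA counting distinguishes the alternating mixmers", {
  expect_equal(count_lna(get_oligo("ON2")), 8)
  expect_equal(count_lna(get_oligo("ON2-5'DNA")), 7)
  expect_equal(count_lna(get_oligo("ON1")), 0)
})

test_that("Watson-Crick complement is an antiparallel involution", {
  expect_equal(wc_complement("ggggaaaagaaaaaagatc"), "gatcttttttcttttcccc")
  expect_equal(wc_complement("a"), "t")
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- paste0(sample(c("a", "c", "g", "t"), sample(1:40, 1), replace = TRUE),
                  collapse = "")
      expect_equal(wc_complement(wc_complement(s)), s)
    }
  })
  expect_error(wc_complement("acgn"), class = "lnahelix_parse_error")
})

test_that("parallel Hoogsteen complement maps A->T, G->C+ position-wise", {
  h <- hoogsteen_parallel_complement("ggaaaagaaaaaaga")
  expect_equal(attr(h, "sequence"), "ccttttcttttttct")  # = ON1
  expect_equal(nrow(h), 15)
  expect_true(all(h$base %in% c("T", "C")))
  expect_true(all(h$protonated == (h$base == "C")))

  h2 <- hoogsteen_parallel_complement("gaagaagaagaagaa")
  expect_equal(attr(h2, "sequence"), "cttcttcttcttctt")  # = ON4 base letters

  h3 <- hoogsteen_parallel_complement("g")
  expect_equal(h3$base, "C")
  expect_true(h3$protonated)

  expect_error(hoogsteen_parallel_complement("gat"),
               "position 3", class = "lnahelix_parse_error")
})

test_that("TFO binding sites are located uniquely on the purine strand", {
  ds45 <- get_target("c-MYC_DS45")
  expect_equal(find_tfo_binding_site(ds45, get_oligo("ON2")), c(16L, 30L))
  ds19 <- get_target("c-MYC_DS19")
  expect_equal(find_tfo_binding_site(ds19, get_oligo("ON1")), c(3L, 17L))
  expect_error(find_tfo_binding_site(ds19, "aaaaa"), class = "lnahelix_parse_error")
  expect_null(find_tfo_binding_site(ds19, "ccccccccc"))
  # a repeated tract is ambiguous
  dup <- duplex_target("ggaaggaagg")
  expect_error(find_tfo_binding_site(dup, "cctt"), "ambiguous",
               class = "lnahelix_ambiguous_site_error")
})

test_that("duplex targets validate complementarity and flag hetero-duplexes", {
  expect_error(duplex_target("ggga", "tccd"), class = "lnahelix_parse_error")
  expect_error(duplex_target("ggga", "ttcc"), "mismatch", class = "lnahelix_duplex_error")
  tab <- paper_targets()
  for (i in seq_len(nrow(tab))) {
    d <- get_target(tab$name[i])
    expect_equal(nt_length(d$purine), tab$length[i], info = tab$name[i])
    expect_equal(d$hetero, grepl("Hetero", tab$name[i]), info = tab$name[i])
  }
})

test_that("hybridization ratios reproduce reported integer ladders", {
  expect_equal(hybridization_ratio(5e-9, 2e-6), 400)
  expect_equal(hybridization_ratio(5e-9, 0.06e-6), 12)
  ons <- c(0.06, 0.09, 0.125, 0.25, 0.5, 1, 2) * 1e-6
  expect_equal(hybridization_ratio(rep(5e-9, 7), ons), c(12, 18, 25, 50, 100, 200, 400))
  expect_equal(hybridization_ratio(3.3e-7, 3.3e-7), 1)
  # far from an integer: exact value is preserved
  expect_equal(hybridization_ratio(1, 2.5), 2.5)
  expect_error(hybridization_ratio(0, 1), class = "lnahelix_value_error")
})

test_that("FASTA export round-trips bases and chemistry via the sidecar", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fasta")
  oligos <- list(ON2 = get_oligo("ON2"), ON1 = get_oligo("ON1"))
  write_oligo_fasta(oligos, path)
  back <- read_oligo_fasta(path)
  expect_equal(lnahelix:::oligo_bases(back$ON2), lnahelix:::oligo_bases(oligos$ON2))
  expect_equal(back$ON2$chemistry, oligos$ON2$chemistry)
  expect_equal(back$ON1$chemistry, oligos$ON1$chemistry)
})
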