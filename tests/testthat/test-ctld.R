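test_that("all observed WIGL-like variants satisfy the pattern", {
  expect_true(all(matchesWiglPattern(
    c("WIGL", "WLGL", "WVGL", "WIGV", "WLGF"))))
  expect_false(any(matchesWiglPattern(
    c("AIGL", "WAGL", "WIAL", "WIGW", "WIG", "WIGLL"))))
})

test_that("the scanner recovers a hand-built domain with exact coordinates", {
  set.seed(107)
  tpl <- makeTemplate(g1 = 25, g2 = 55, g3 = 20, wigl = "WVGL")
  u <- UnigeneSet(setNames(plantCtld(tpl, 1), "u1"), sample = "S")
  d <- scanCtld(u)
  d <- d[d$frame == "+1", ]
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 0L)
  expect_equal(c(d$cys1, d$cys2, d$cys3, d$cys4), c(0L, 25L, 80L, 100L))
  expect_equal(d$wigl, "WVGL")
  expect_equal(d$domain_seq, tpl)
})

test_that("fewer than four cysteines yields no domain", {
  set.seed(109)
  tpl <- makeTemplate()
  broken <- sub("C", "A", tpl)          # removes the first cysteine
  u <- UnigeneSet(setNames(plantCtld(makeTemplate(), 1), "ok"),
                  sample = "S")
  expect_equal(nrow(scanCtld(UnigeneSet(
    setNames(HolobiontEST:::.revTranslate(broken), "u1"),
    sample = "S"))), 0L)
})

test_that("concatenated domains are split into non-overlapping windows", {
  set.seed(113)
  t1 <- makeTemplate(wigl = "WIGL")
  t2 <- makeTemplate(wigl = "WLGF")
  linker <- paste(sample(setdiff(strsplit("ARNDQEGHILKMFPSTYV", "")[[1]],
                                 ""), 20, replace = TRUE), collapse = "")
  pep <- paste0("MASG", t1, linker, t2, "GSA")
  u <- UnigeneSet(setNames(HolobiontEST:::.revTranslate(pep), "u1"),
                  sample = "S")
  d <- scanCtld(u)
  d <- d[d$frame == "+1", ]
  expect_equal(nrow(d), 2L)
  expect_true(d$start[2] >= d$end[1])           # non-overlapping
  expect_equal(d$wigl, c("WIGL", "WLGF"))
})

test_that("sugar motifs classify as in natural CTLD variants", {
  set.seed(127)
  ref <- referenceCtldAnchor()
  mk <- function(sugar) {
    tpl <- anchorVariant(sugar = sugar)
    u <- UnigeneSet(setNames(plantCtld(tpl, 1), "u1"), sample = "S")
    d <- scanCtld(u, reference = ref)
    d[d$frame == "+1", ]
  }
  epn <- mk("EPN")
  expect_equal(epn$sugar_motif, "EPN")
  expect_equal(epn$sugar_class, "glucose/mannose")
  lnd <- mk("LND")
  expect_equal(lnd$sugar_motif, "LND")
  expect_equal(lnd$sugar_class, "galactose")
  for (variant in c("DSS", "WSD", "VND")) {
    d <- mk(variant)
    expect_equal(d$sugar_class, "variant")
    expect_equal(d$sugar_motif, variant)
  }
  short <- classifySugar("CAACC", 2, 4)
  expect_equal(short$sugar_class, "variant")
  expect_equal(short$sugar_motif, "")
})

test_that("dedup collapses identical domains and keeps distinct ones", {
  set.seed(131)
  tpl <- makeTemplate()
  other <- makeTemplate()
  dom <- function(id, seq) data.frame(
    unigene = id, sample = "S", frame = "+1", start = 0L,
    end = nchar(seq), cys1 = 0L, cys2 = 25L, cys3 = 80L, cys4 = 100L,
    wigl = "WIGL", sugar_motif = "EPN", sugar_class = "glucose/mannose",
    domain_seq = seq, stringsAsFactors = FALSE)
  d3 <- rbind(dom("a", tpl), dom("b", tpl), dom("c", tpl))
  expect_equal(nrow(dedupeDomains(d3)), 1L)
  d2 <- rbind(dom("a", tpl), dom("b", other))
  expect_equal(nrow(dedupeDomains(d2)), 2L)
  # idempotent
  once <- dedupeDomains(d3)
  expect_equal(dedupeDomains(once), once)
})

test_that("lowering the dedup threshold never increases the count", {
  set.seed(137)
  tpl <- makeTemplate()
  vary <- function(k) {
    ch <- strsplit(tpl, "")[[1]]
    free <- setdiff(seq_along(ch), c(1, 26, 81, 101, 11:14, 61:63))
    pos <- sample(free, k)
    ch[pos] <- sample(setdiff(c("A", "G", "L", "S", "T", "V"), ch[pos][1]),
                      k, replace = TRUE)
    paste(ch, collapse = "")
  }
  doms <- do.call(rbind, lapply(1:8, function(i) data.frame(
    unigene = paste0("u", i), sample = "S", frame = "+1", start = 0L,
    end = 101L, cys1 = 0L, cys2 = 25L, cys3 = 80L, cys4 = 100L,
    wigl = "WIGL", sugar_motif = "EPN", sugar_class = "glucose/mannose",
    domain_seq = vary(sample(1:30, 1)), stringsAsFactors = FALSE)))
  counts <- vapply(c(0.5, 0.8, 0.95, 1.0), function(th)
    nrow(dedupeDomains(doms, th)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("per-sample WIGL variants are collected as sets", {
  d <- data.frame(sample = c("S1", "S1", "S1", "S2"),
                  wigl = c("WIGL", "WIGL", "WVGL", "WIGV"))
  v <- wiglVariants(d)
  expect_equal(v$S1, c("WIGL", "WVGL"))
  expect_equal(v$S2, "WIGV")
  expect_equal(length(wiglVariants(d[0, ])), 0L)
})

test_that("cysteine-free negative transcripts yield no domains", {
  p <- sampleProfile("S1", n_reads = 0, rrna_fraction = 0,
                     n_negative_ctld = 25)
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 139))
  neg <- sim@reads[sim@truthReads$id[sim@truthReads$negative]]
  expect_equal(nrow(scanCtld(neg)), 0L)
})

test_that("grammar-only scan finds a superset of seeded-mode domains", {
  p <- sampleProfile("S1", n_reads = 10, rrna_fraction = 0,
                     n_planted_ctld = 2, n_redundant_copies = 0)
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 149))
  reads <- lengthFilter(trimPolyA(sim@reads))$kept
  seeds <- searchHomology(reads, sim@proteinRefs,
                          scoringScheme("protein"), min_score = 60)
  seeded <- scanCtld(reads, seed_hits = seeds)
  full <- scanCtld(reads)
  key <- function(d) paste(d$unigene, d$frame, d$start, d$end)
  expect_true(all(key(seeded) %in% key(full)))
  expect_equal(nrow(seeded), 2L)
})
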