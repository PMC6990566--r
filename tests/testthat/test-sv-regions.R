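vcfFixture <- function(path) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "S01", "S02", "S03", sep = "\t"),
        paste("chr1", "1001", "del_a", "N", "<DEL>", ".", "PASS",
              "SVTYPE=DEL;END=3000", "GT", "0/0", "0/1", "1/1",
              sep = "\t"),
        paste("chr1", "5001", "del_b", "N", "<DEL>", ".", "PASS",
              "SVTYPE=DEL;END=6000", "GT", "./.", "0|1", "0/0",
              sep = "\t"),
        paste("chr1", "9001", "dup_c", "N", "<DUP>", ".", "PASS",
              "SVTYPE=DUP;END=12000", "GT", "0/1", "0/1", "0/1",
              sep = "\t"),
        paste("chr1", "15001", "inv_d", "N", "<INV>", ".", "PASS",
              "SVTYPE=INV;END=20000", "GT", "1/1", "0/0", "0/1",
              sep = "\t")), path)
    path
}

test_that("VCF genotypes become 0/1/2 dosages with missing handled", {
    f <- vcfFixture(withr::local_tempfile(fileext = ".vcf"))
    svs <- readSVGenotypes(f)
    expect_equal(length(svs), 3L)  # DUP excluded
    expect_setequal(S4Vectors::mcols(svs)$svtype, c("DEL", "DEL", "INV"))
    d <- svDosage(svs)
    expect_equal(unname(d["del_a", ]), c(0L, 1L, 2L))
    expect_true(is.na(d["del_b", "S01"]))
    expect_equal(d["del_b", "S02"], 1L)
    # END is honoured
    expect_equal(GenomicRanges::end(svs["del_a"]), 3000)
    expect_error(readSVGenotypes(f, samples = c("S01", "S99")), "S99")
})

test_that("common-deletion filter applies carrier and size rules", {
    mk <- function(id, dosage, len) {
        delGRanges(10001, 10000 + len, dosage, id = id)
    }
    svs <- suppressWarnings(c(
        mk("three_carriers", c(1, 1, 2, 0, 0), 5000),
        mk("two_carriers", c(1, 0, 1, 0, 0), 5000),
        mk("big", c(1, 1, 1, 1, 0), 12000)))
    kept <- filterCommonDeletions(svs, minCarriers = 3)
    expect_setequal(S4Vectors::mcols(kept)$svId,
                    c("three_carriers", "big"))
    # size window keeps only the 12 kb record
    kept2 <- filterCommonDeletions(svs, minCarriers = 0, sizeMin = 10000)
    expect_equal(S4Vectors::mcols(kept2)$svId, "big")
    # minCarriers = 0 and no bounds is the identity on deletions
    expect_equal(length(filterCommonDeletions(svs, minCarriers = 0)), 3L)
    expect_warning(filterCommonDeletions(svs, minCarriers = 10),
                   "exceeds sample count")
})

test_that("SV-to-bin mapping follows the half-open 40 kb convention", {
    # the worked example: an ~80 kb deletion at chr1:196,728,877-196,808,865
    cfhr <- delGRanges(196728877, 196808865, c(0, 1, 2))
    expect_equal(svToBins(cfhr, 40000L), 4918:4920)
    expect_equal(svToBins(delGRanges(1, 1, 0), 40000L), 0)
    # start exactly on a bin edge opens the next bin
    expect_equal(min(svToBins(delGRanges(40001, 50000, 0), 40000L)), 1)
})

test_that("bin mapping matches a per-base brute-force oracle", {
    set.seed(13)
    for (rep in 1:20) {
        bs <- sample(c(10L, 25L, 40L), 1)
        s <- sample(1:500, 1)
        e <- s + sample(0:200, 1)
        sv <- delGRanges(s, e, 0)
        oracle <- sort(unique(floor(((s:e) - 1) / bs)))
        expect_equal(svToBins(sv, bs), oracle)
    }
})

test_that("span and flank pair sets enumerate as expected", {
    # deletion covering bin 10 only, two flank bins per side
    sv <- delGRanges(10 * 40000 + 1, 11 * 40000, c(0, 1, 2))
    spec <- defineRegions(sv, nFlank = 2L, nBinsTotal = 100)
    expect_equal(spec$maskedBins, 10L)
    expect_equal(spec$leftFlank, c(8L, 9L))
    expect_equal(spec$rightFlank, c(11L, 12L))
    span <- apply(spec$spanPairs, 1, paste, collapse = "-")
    expect_setequal(span, c("8-11", "9-11", "8-12", "9-12"))
    flank <- apply(spec$flankPairs, 1, paste, collapse = "-")
    expect_setequal(flank, c("8-9", "11-12"))
    # an extra mask shifts the flank outward instead of shrinking it
    spec2 <- defineRegions(sv, nFlank = 2L, extraMask = 9L,
                           nBinsTotal = 100)
    expect_equal(spec2$leftFlank, c(7L, 8L))
    # default width is six bins = 240 kb at 40 kb resolution
    spec6 <- defineRegions(sv, nBinsTotal = 100)
    expect_equal(spec6$flankWidth * 40000, 240000)
    expect_equal(length(spec6$leftFlank), 6L)
})

test_that("edge loci with no flanks on either side are untestable", {
    sv <- delGRanges(1, 3 * 40000, c(0, 1))
    expect_error(defineRegions(sv, nFlank = 2L, nBinsTotal = 3),
                 "untestable locus")
    # one-sided locus is still allowed: span empty, flank from one side
    spec <- defineRegions(sv, nFlank = 2L, nBinsTotal = 10)
    expect_equal(nrow(spec$spanPairs), 0L)
    expect_equal(spec$rightFlank, c(3L, 4L))
})

test_that("region pair sets never touch masked bins (fuzz)", {
    set.seed(29)
    for (rep in 1:25) {
        start <- sample(5:60, 1)
        len <- sample(1:4, 1)
        sv <- delGRanges(start * 40000 + 1, (start + len) * 40000,
                         c(0, 1, 2))
        extra <- sample(0:70, sample(0:6, 1))
        spec <- tryCatch(
            defineRegions(sv, nFlank = sample(2:6, 1), extraMask = extra,
                          nBinsTotal = 71),
            error = function(e) NULL)
        if (is.null(spec)) next
        pairs <- rbind(spec$spanPairs, spec$flankPairs)
        expect_false(any(pairs %in% spec$maskedBins))
        # span pairs straddle the masked SV range
        if (nrow(spec$spanPairs)) {
            expect_true(all(spec$spanPairs[, 1] < start))
            expect_true(all(spec$spanPairs[, 2] > start + len - 1))
        }
        # span and flank sets are disjoint
        key <- function(p) apply(p, 1, paste, collapse = "-")
        expect_length(intersect(key(spec$spanPairs),
                                key(spec$flankPairs)), 0)
    }
})

test_that("TAD-boundary overlap uses the 1 bp rule", {
    bd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
    expect_equal(classifyTadBoundary(delGRanges(100, 200, 0), bd), "TB")
    expect_equal(classifyTadBoundary(delGRanges(100, 199, 0), bd),
                 "NonTB")
})

test_that("region statistics honour missingness and the stat switch", {
    sv <- delGRanges(10 * 40000 + 1, 11 * 40000, c(0, 1, 2))
    spec <- defineRegions(sv, nFlank = 2L, nBinsTotal = 20)
    m <- cmFromPairs(20, rbind(c(8, 11), c(9, 11), c(8, 12), c(9, 12),
                               c(8, 9), c(11, 12)),
                     c(2, 4, 2, 4, 1, 10))
    expect_equal(regionStat(m, spec, "span", "mean"), 3)
    expect_equal(regionStat(m, spec, "flank", "median"), 5.5)
    # all span pairs missing -> NA
    m2 <- cmFromPairs(20, rbind(c(8, 11), c(8, 9), c(11, 12)),
                      c(5, 1, 2),
                      missing = replace(rep(FALSE, 20), c(12, 13), TRUE))
    expect_true(is.na(regionStat(m2, spec, "span")))
    specEmpty <- spec
    specEmpty$spanPairs <- spec$spanPairs[0, , drop = FALSE]
    expect_error(regionStat(m, specEmpty, "span"), "empty span")
})

test_that("eQTL annotation joins by id or exact coordinates", {
    svs <- c(delGRanges(1000, 2000, c(0, 1), id = "d1"),
             delGRanges(5000, 6000, c(0, 1), id = "d2"),
             delGRanges(9000, 9500, c(0, 1), id = "d3"))
    tab <- data.frame(
        sv_id = c("d1", "d1", "zzz"),
        chrom = c("chrX", "chrX", "chr1"),
        start = c(1, 1, 9000), end = c(2, 2, 9500),
        gene = c("GENE1", "GENE2", "GENE3"))
    out <- annotateEqtl(svs, tab)
    g <- S4Vectors::mcols(out)$eqtlGenes
    expect_equal(sort(g[["d1"]]), c("GENE1", "GENE2"))  # duplicates kept
    expect_length(g[["d2"]], 0)                          # no match
    expect_equal(g[["d3"]], "GENE3")                     # coordinate match
    expect_error(annotateEqtl(svs, data.frame(x = 1)), "malformed")
})
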