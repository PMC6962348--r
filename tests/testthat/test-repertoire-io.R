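test_that("ImmunoSeq dialect drops null productive_frequency rows and renormalises", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(
    nucleotide = c("TGTGCCAGCTTT", "TGTGCCTCATTT", "TGTGCCGGGTTT",
                   "TGTGCCAAATTT"),
    amino_acid = c("CASF", "CASF", "CAGF", "CAKF"),
    v_gene = c("TCRBV05-01", "TCRBV05-01", "TCRBV12", "TCRBV19"),
    v_family = c("TCRBV05", "TCRBV05", "TCRBV12", "TCRBV19"),
    reads = c(10, 20, 30, 40),
    productive_frequency = c("0.1", "0.2", "null", "0.4")), path)
  rep <- read_clonotype_table(path, dialect = "immunoseq")
  expect_equal(nrow(rep$clones), 3L)
  expect_equal(rep$total_reads, 70)
  expect_equal(sum(rep$clones$frequency), 1, tolerance = 1e-12)
  expect_setequal(rep$clones$read_count, c(10, 20, 40))
  expect_false("CAGF" %in% rep$clones$cdr3_aa)
})

test_that("unresolved v_gene falls back to the v_family value", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(
    nucleotide = c("TGTGCCAGCTTT", "TGTGCCTTGTTT"),
    amino_acid = c("CASF", "CALF"),
    v_gene = c("unresolved", "TCRBV07-09"),
    v_family = c("TCRBV12", "TCRBV07"),
    reads = c(5, 5),
    productive_frequency = c("0.5", "0.5")), path)
  rep <- read_clonotype_table(path, dialect = "immunoseq")
  expect_setequal(rep$clones$v_gene, c("TCRBV12", "TCRBV07-09"))
})

test_that("rows sharing (cdr3_nt, v_gene) are merged by summing reads", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(
    junction = c("TGTGCCAGCTTT", "TGTGCCAGCTTT", "TGTGCCTCATTT"),
    junction_aa = c("CASF", "CASF", "CASF"),
    v_call = c("TRBV12-3*01", "TRBV12-3*02", "TRBV12-3"),
    duplicate_count = c(10, 5, 7),
    productive = c("T", "T", "T")), path)
  rep <- read_clonotype_table(path, dialect = "airr")
  expect_equal(nrow(rep$clones), 2L)
  merged <- rep$clones[rep$clones$cdr3_nt == "TGTGCCAGCTTT", ]
  expect_equal(merged$read_count, 15)
  expect_equal(rep$total_reads, 22)
})

test_that("format errors name the offending column and empty tables fail", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(amino_acid = "CASF", reads = 1), path)
  expect_error(read_clonotype_table(path, "immunoseq"), "v_gene")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(
    nucleotide = "TGTGCCAGCTTT", amino_acid = "CASF", v_gene = "TCRBV05",
    v_family = "TCRBV05", reads = 3, productive_frequency = "null"), path2)
  expect_error(read_clonotype_table(path2, "immunoseq"), "empty repertoire")
})

test_that("strip_allele follows the before-the-star rule and is idempotent", {
  expect_equal(strip_allele("TRBV12-3*01"), "TRBV12-3")
  expect_equal(strip_allele("TCRBV05-01"), "TCRBV05-01")
  expect_equal(strip_allele("TRBV7-9*03"), "TRBV7-9")
  calls <- c("TRBV2*01", "TRBV6-5", "TRBV20-1*03", "TRBV12*02*99")
  expect_equal(strip_allele(strip_allele(calls)), strip_allele(calls))
  expect_error(strip_allele(""), "non-empty")
})

test_that("translate_cdr3 matches an independent codon-table oracle", {
  expect_equal(translate_cdr3("TGTGCC"), "CA")
  expect_true(has_stop(translate_cdr3("TGATGTGCC")))
  set.seed(11)
  gc <- Biostrings::GENETIC_CODE
  for (i in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    oracle <- paste(gc[substring(nt, seq(1, 28, 3), seq(3, 30, 3))],
                    collapse = "")
    expect_equal(translate_cdr3(nt), oracle)
  }
  expect_error(translate_cdr3("TGTGC"), "frame")
  expect_error(translate_cdr3("TGTGCN"), "non-ACGT")
})

test_that("effective CDR3 length removes the two anchor residues", {
  expect_equal(effective_cdr3_length("CASSLGQAYEQYF"), 11L)
  expect_equal(effective_cdr3_length("CF"), 0L)
  expect_equal(effective_cdr3_length("CASSF"), 3L)
  expect_error(effective_cdr3_length("C"), "degenerate")
})

test_that("write/read round-trips preserve clones, counts, and frequencies", {
  for (seed in 1:25) {
    sim <- simulate_repertoire(simulation_config(
      n_clones = 40, depth = 2000, clonality_target = runif(1, 0, 0.3),
      n_true_groups = 3, seed = seed))
    for (dialect in c("immunoseq", "airr")) {
      path <- withr::local_tempfile(fileext = ".tsv")
      write_clonotype_table(sim$repertoire, path, dialect)
      back <- read_clonotype_table(path, dialect)
      key <- function(r) {
        cl <- r$clones[order(r$clones$cdr3_nt, r$clones$v_gene), ]
        cl[, c("cdr3_nt", "cdr3_aa", "v_gene", "read_count", "frequency")]
      }
      expect_equal(key(back), key(sim$repertoire), ignore_attr = TRUE)
      expect_equal(back$total_reads, sim$repertoire$total_reads)
      expect_equal(sum(back$clones$frequency), 1, tolerance = 1e-9)
    }
  }
  expect_error(write_clonotype_table(
    structure(list(clones = data.frame()), class = "tcr_repertoire"),
    tempfile()), "empty")
})

test_that("optional out-of-frame filter drops stop-containing junctions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raw_table(data.frame(
    junction = c("TGTGCCAGCTTT", "TGTTGAAGCTTT", "TGTGCCAGCTT"),
    junction_aa = c("CASF", "C*SF", "CASF"),
    v_call = c("TRBV1", "TRBV2", "TRBV3"),
    duplicate_count = c(1, 1, 1),
    productive = c("T", "F", "F")), path)
  kept <- read_clonotype_table(path, "airr", drop_out_of_frame = TRUE)
  expect_equal(kept$clones$v_gene, "TRBV1")
  all_rows <- read_clonotype_table(path, "airr")
  expect_equal(nrow(all_rows$clones), 3L)
})
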