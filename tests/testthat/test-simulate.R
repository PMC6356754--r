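test_that("simulated genomes hit their GC target and are seed-determined", {
  g <- simulate_genome(10000, gc = 0.5, seed = 1)
  expect_equal(nchar(g), 10000)
  gc_frac <- function(x) {
    mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  }
  expect_lt(abs(gc_frac(g) - 0.5), 0.02)
  expect_identical(g, simulate_genome(10000, gc = 0.5, seed = 1))
  expect_false(identical(g, simulate_genome(10000, gc = 0.5, seed = 2)))
  expect_gt(gc_frac(simulate_genome(10000, gc = 0.99, seed = 3)), 0.95)
})

test_that("error-free simulation yields exact genome substrings", {
  g <- simulate_genome(20000, seed = 5)
  cfg <- sim_config(n_reads = 30, read_length_mean = 500,
                    read_length_min = 100, read_length_max = 2000,
                    sub_rate = 0, ins_rate = 0, del_rate = 0,
                    error_jitter = c(1, 1))
  sim <- simulate_reads(g, cfg, seed = 6)
  expect_true(all(sim$truth$true_identity == 100))
  expect_true(all(sim$truth$n_subs + sim$truth$n_ins + sim$truth$n_del == 0))
  for (i in seq_len(10)) {
    tr <- sim$truth[i, ]
    tmpl <- substr(g, tr$start, tr$start + tr$ref_span - 1)
    if (tr$strand == "-") {
      tmpl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tmpl)))
    }
    expect_identical(sim$reads$bases[i], tmpl)
  }
})

test_that("mean true identity matches the edit-model expectation", {
  # with identity = matches / reference span, insertions consume no span,
  # so E[identity] = 100 * (1 - sub - del)
  g <- simulate_genome(60000, seed = 8)
  cfg <- sim_config(n_reads = 500, read_length_mean = 8000,
                    read_length_min = 1000, read_length_max = 20000,
                    sub_rate = 0.05, ins_rate = 0.03, del_rate = 0.03,
                    homopolymer_indel_multiplier = 1,
                    error_jitter = c(1, 1))
  sim <- simulate_reads(g, cfg, seed = 9)
  expect_lt(abs(mean(sim$truth$true_identity) - 92.0), 1.0)
  # edit counts are consistent with the recorded identity
  expect_equal(sim$truth$true_identity,
               (sim$truth$ref_span - sim$truth$n_subs - sim$truth$n_del) /
                 sim$truth$ref_span * 100)
  expect_equal(sim$truth$read_length,
               sim$truth$ref_span - sim$truth$n_del + sim$truth$n_ins)
})

test_that("homopolymer multiplier inflates indels; sub rate drives identity", {
  g <- paste0(simulate_genome(20000, seed = 10),
              strrep("A", 500), strrep("T", 500)) # guarantee long runs
  base <- function(mult) {
    sim_config(n_reads = 100, read_length_mean = 2000,
               read_length_min = 500, read_length_max = 8000,
               sub_rate = 0.02, ins_rate = 0.02, del_rate = 0.02,
               homopolymer_indel_multiplier = mult,
               error_jitter = c(1, 1))
  }
  flat <- simulate_reads(g, base(1), seed = 11)$truth
  boosted <- simulate_reads(g, base(10), seed = 11)$truth
  expect_gt(sum(boosted$n_ins + boosted$n_del),
            sum(flat$n_ins + flat$n_del))

  more_subs <- sim_config(n_reads = 100, read_length_mean = 2000,
                          read_length_min = 500, read_length_max = 8000,
                          sub_rate = 0.10, ins_rate = 0.02, del_rate = 0.02,
                          homopolymer_indel_multiplier = 1,
                          error_jitter = c(1, 1))
  noisy <- simulate_reads(g, more_subs, seed = 11)$truth
  expect_lt(mean(noisy$true_identity), mean(flat$true_identity))
})

test_that("simulation is deterministic per seed and validates its config", {
  g <- simulate_genome(10000, seed = 12)
  cfg <- sim_config(n_reads = 20, read_length_mean = 500,
                    read_length_min = 100, read_length_max = 2000)
  a <- simulate_reads(g, cfg, seed = 13)
  b <- simulate_reads(g, cfg, seed = 13)
  expect_identical(a, b)
  c <- simulate_reads(g, cfg, seed = 14)
  expect_false(identical(a$reads$bases, c$reads$bases))

  expect_error(simulate_reads(substr(g, 1, 1000), cfg), "genome")
  expect_error(sim_config(sub_rate = 0.6, ins_rate = 0.3, del_rate = 0.2))
  expect_error(sim_config(read_length_min = 5000, read_length_mean = 100))
})

test_that("realigning simulated reads recovers the recorded identity", {
  g <- simulate_genome(20000, seed = 15)
  cfg <- sim_config(n_reads = 50, read_length_mean = 800,
                    read_length_min = 400, read_length_max = 2000,
                    error_jitter = c(0.3, 1.0))
  sim <- simulate_reads(g, cfg, seed = 16)
  # cheap gaps make the optimal alignment maximise matches, the quantity the
  # truth table records; the realignment may still beat the generating edit
  # script by a small margin
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    tmpl <- substr(g, tr$start, tr$start + tr$ref_span - 1)
    if (tr$strand == "-") {
      tmpl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tmpl)))
    }
    pa <- Biostrings::pairwiseAlignment(
      sim$reads$bases[i], tmpl, type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1
    )
    realigned <- Biostrings::nmatch(pa) / tr$ref_span * 100
    expect_lt(abs(realigned - tr$true_identity), 2)
  }
})

test_that("the benchmark separates classes and documents its ground truth", {
  bench <- small_benchmark()
  expect_setequal(names(bench), c("genome", "raw", "corrected", "truth"))
  expect_equal(nrow(bench$truth), nrow(bench$raw) + nrow(bench$corrected))
  expect_setequal(bench$truth$read_id,
                  c(bench$raw$read_id, bench$corrected$read_id))

  id_of <- function(reads) {
    bench$truth$true_identity[match(reads$read_id, bench$truth$read_id)]
  }
  expect_gt(mean(id_of(bench$corrected)), mean(id_of(bench$raw)))
  expect_true(all(nchar(bench$corrected$bases) >= 1500)) # HQ min length 2000 pre-error

  # the files survive a round trip through the sequence layer
  fa <- tempfile(fileext = ".fasta")
  write_sequences(bench$raw, fa)
  expect_equal(nrow(read_sequences(fa)), nrow(bench$raw))
})

test_that("homopolymer-biased errors shift AAA/TTT content between classes", {
  bench <- small_benchmark()
  contrast <- feature_contrast(bench$raw, bench$corrected)
  aaa <- contrast$diff[contrast$kmer == "AAA"]
  ttt <- contrast$diff[contrast$kmer == "TTT"]
  expect_true(abs(aaa) > 0)
  expect_true(abs(ttt) > 0)
  # strand symmetry of the genome makes the two run k-mers move together
  expect_equal(sign(aaa), sign(ttt))
  expect_s3_class(plot_feature_contrast(contrast), "ggplot")
})

test_that("the truth-derived PAF reproduces the simulator's identities", {
  bench <- small_benchmark()
  paf <- tempfile(fileext = ".paf")
  write_truth_paf(bench$truth, paf, nchar(bench$genome))
  aln <- parse_alignments(paf)
  expect_equal(nrow(aln), nrow(bench$truth))
  ident <- alignment_identity(aln$matches, aln$overlap_length)
  expect_equal(ident[match(bench$truth$read_id, aln$read_id)],
               bench$truth$true_identity, tolerance = 1e-9)
})
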