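#' Simulate a random reference genome
#'
#' I.i.d. bases with a target GC content; deterministic for a given seed.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc Target GC fraction, in `(0, 1)`.
#' @param seed Integer seed.
#' @return A single base string over `ACGT`.
#' @examples
#' substr(simulate_genome(50, gc = 0.5, seed = 1), 1, 20)
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 0L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Configuration for the long-read simulator
#'
#' Bundles the knobs of the error model. Read lengths are log-normal
#' (`sdlog = 0.6`, approximating the long right tail of real long-read
#' length distributions) clamped to `[read_length_min, read_length_max]`.
#' Per-base error probabilities are scaled per read by a jitter factor drawn
#' uniformly from `error_jitter`, which spreads true identity across reads
#' the way real flowcells do; inside homopolymer runs of length >= 3 the
#' insertion and deletion rates are additionally multiplied by
#' `homopolymer_indel_multiplier`, emulating the platform bias toward
#' indels of the same continuous base.
#'
#' @param n_reads Number of reads.
#' @param read_length_mean,read_length_min,read_length_max Length
#'   distribution parameters in bases.
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion probabilities (before jitter), each in `[0, 1)` with
#'   `sub + ins + del < 1`.
#' @param homopolymer_indel_multiplier Factor (>= 1) applied to the indel
#'   rates inside homopolymer runs of length >= 3.
#' @param error_jitter Length-2 range of the per-read uniform error scale.
#' @param id_prefix Prefix of the generated read identifiers.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 2000,
                       read_length_mean = 4000,
                       read_length_min = 100,
                       read_length_max = 20000,
                       sub_rate = 0.07,
                       ins_rate = 0.04,
                       del_rate = 0.04,
                       homopolymer_indel_multiplier = 3,
                       error_jitter = c(0.1, 2.6),
                       id_prefix = "read") {
  stopifnot(
    n_reads >= 1, read_length_min >= 1,
    read_length_min <= read_length_mean,
    read_length_mean <= read_length_max,
    sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
    sub_rate < 1, ins_rate < 1, del_rate < 1,
    sub_rate + ins_rate + del_rate < 1,
    homopolymer_indel_multiplier >= 1,
    length(error_jitter) == 2, all(error_jitter >= 0),
    error_jitter[1] <= error_jitter[2]
  )
  structure(
    list(n_reads = n_reads,
         read_length_mean = read_length_mean,
         read_length_min = read_length_min,
         read_length_max = read_length_max,
         sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
         homopolymer_indel_multiplier = homopolymer_indel_multiplier,
         error_jitter = error_jitter,
         id_prefix = id_prefix),
    class = "sim_config"
  )
}

#' Simulate long reads with homopolymer-biased errors and ground truth
#'
#' Draws reads from a genome and corrupts them with a per-position edit
#' script: each reference position is deleted, substituted (to a different
#' base) or copied; after each surviving position an insertion may follow,
#' duplicating the preceding base with probability 0.5 (else a uniform
#' base) to mimic homopolymer expansion. The exact edit counts are recorded,
#' and the ground-truth identity of each read is defined exactly as the
#' alignment metric downstream: matched bases divided by the consumed
#' reference span, as a percentage.
#'
#' @param genome Reference base string (from [simulate_genome()] or real).
#' @param config A [sim_config()].
#' @param seed Integer seed; the full output is deterministic given the seed.
#' @param source Source tag for the generated reads.
#' @return A list with `reads` (read tibble) and `truth` (tibble:
#'   `read_id`, `true_identity`, `read_length`, `ref_span`, `start`,
#'   `strand`, `n_subs`, `n_ins`, `n_del`).
#' @export
simulate_reads <- function(genome, config = sim_config(), seed = 0L,
                           source = "simulated") {
  stopifnot(is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  if (G < config$read_length_max) {
    abort(paste0("genome (", G, " bp) shorter than read_length_max (",
                 config$read_length_max, " bp)"))
  }
  with_seed(seed, {
    n <- config$n_reads
    meanlog <- log(config$read_length_mean) - 0.6^2 / 2
    lens <- pmin(pmax(round(rlnorm(n, meanlog, 0.6)),
                      config$read_length_min), config$read_length_max)
    starts <- floor(runif(n, 1, G - lens + 1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    jit <- runif(n, config$error_jitter[1], config$error_jitter[2])

    res <- purrr::pmap(
      list(lens, starts, strands, jit, seq_len(n)),
      function(L, st, strand, j, i) {
        tmpl <- substr(genome, st, st + L - 1)
        if (strand == "-") tmpl <- revcomp(tmpl)
        corrupt_read(tmpl, config, j)
      }
    )
    ids <- sprintf("%s_%05d", config$id_prefix, seq_len(n))
    reads <- tibble::tibble(
      read_id = ids,
      bases = vapply(res, `[[`, "", "bases"),
      qualities = NA_character_,
      source = source
    )
    truth <- tibble::tibble(
      read_id = ids,
      true_identity = vapply(res, `[[`, 0, "true_identity"),
      read_length = nchar(reads$bases),
      ref_span = lens,
      start = as.integer(starts),
      strand = strands,
      n_subs = vapply(res, `[[`, 0L, "n_subs"),
      n_ins = vapply(res, `[[`, 0L, "n_ins"),
      n_del = vapply(res, `[[`, 0L, "n_del")
    )
    empty <- truth$read_length == 0L
    if (any(empty)) {
      # a fully deleted read cannot be written; keep a single N placeholder
      reads$bases[empty] <- "N"
      truth$read_length[empty] <- 1L
    }
    list(reads = reads, truth = truth)
  })
}

# apply the edit model to one template; RNG state flows from the caller
corrupt_read <- function(template, config, jitter) {
  L <- nchar(template)
  chars <- strsplit(template, "", fixed = TRUE)[[1]]

  mult <- rep(1, L)
  if (config$homopolymer_indel_multiplier > 1 && L >= 3) {
    r <- rle(chars)
    mult <- rep(ifelse(r$lengths >= 3, config$homopolymer_indel_multiplier, 1),
                r$lengths)
  }
  s <- min(config$sub_rate * jitter, 0.95)
  d <- pmin(config$del_rate * jitter * mult, 0.95)
  u <- runif(L)
  del <- u < d
  sub <- !del & u < d + s   # u >= 1 is impossible, so overflow self-truncates
  keep <- !del & !sub

  out <- chars
  if (any(sub)) {
    # substitute with one of the three other bases, uniformly
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    idx <- sample.int(3, sum(sub), replace = TRUE)
    base_row <- match(chars[sub], rownames(alt))
    base_row[is.na(base_row)] <- 1L   # N in template: substitute from A's row
    out[sub] <- alt[cbind(base_row, idx)]
  }
  out[del] <- ""

  i_eff <- pmin(config$ins_rate * jitter * mult, 0.95)
  ins <- runif(L) < i_eff & !del     # insertions follow surviving positions
  if (any(ins)) {
    dup <- runif(sum(ins)) < 0.5
    ins_base <- ifelse(dup, out[ins],
                       sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE))
    ins_base[ins_base == ""] <- "A"
    out[ins] <- paste0(out[ins], ins_base)
  }

  list(
    bases = paste(out, collapse = ""),
    true_identity = sum(keep) / L * 100,
    n_subs = sum(sub), n_ins = sum(ins), n_del = sum(del)
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build a self-supervision benchmark: raw reads plus a corrected proxy
#'
#' Generates, from one random genome, a "raw" low-quality read set whose
#' per-read true identity spans roughly 70–99% (mean about 85%, the 2D
#' Nanopore regime) and a "corrected" high-quality proxy set with one fifth
#' of the error rates and a 2,000 bp minimum length, standing in for the
#' output of an error-correction tool. Ground truth covers every read of
#' both sets.
#'
#' @param seed Integer seed driving the genome and both read sets.
#' @param n_raw,n_corrected Read counts of the two sets.
#' @param genome_length Genome size in bases.
#' @param gc Genome GC fraction.
#' @param lq_config,hq_config Optional [sim_config()] overrides for the two
#'   sets; the defaults encode the regime above.
#' @return A list with `genome` (string), `raw` and `corrected` (read
#'   tibbles) and `truth` (tibble covering both sets).
#' @export
make_benchmark <- function(seed = 42L, n_raw = 2000, n_corrected = 1000,
                           genome_length = 100000, gc = 0.5,
                           lq_config = NULL, hq_config = NULL) {
  if (is.null(lq_config)) {
    lq_config <- sim_config(n_reads = n_raw, id_prefix = "raw")
  }
  if (is.null(hq_config)) {
    hq_config <- sim_config(
      n_reads = n_corrected,
      read_length_min = min(2000, lq_config$read_length_max),
      read_length_mean = min(4000, lq_config$read_length_max),
      read_length_max = lq_config$read_length_max,
      sub_rate = lq_config$sub_rate / 5,
      ins_rate = lq_config$ins_rate / 5,
      del_rate = lq_config$del_rate / 5,
      homopolymer_indel_multiplier = lq_config$homopolymer_indel_multiplier,
      error_jitter = c(0.5, 1.5),
      id_prefix = "corr"
    )
  }
  genome <- simulate_genome(genome_length, gc = gc, seed = seed)
  lq <- simulate_reads(genome, lq_config, seed = seed + 1L, source = "raw")
  hq <- simulate_reads(genome, hq_config, seed = seed + 2L,
                       source = "corrected")
  lq$reads$source <- "raw"
  hq$reads$source <- "corrected"
  list(
    genome = genome,
    raw = lq$reads,
    corrected = hq$reads,
    truth = dplyr::bind_rows(lq$truth, hq$truth)
  )
}

#' Write a ground-truth PAF from simulated reads
#'
#' Emits one PAF line per simulated read, derived from the exact edit script
#' rather than a realignment: matches, reference span and block length come
#' straight from the truth table, so evaluation metrics computed from this
#' file agree with the simulator's ground truth by construction.
#'
#' @param truth Truth tibble from [simulate_reads()] or [make_benchmark()].
#' @param path Output PAF path.
#' @param genome_length Length of the source genome (target length column).
#' @param ref_name Reference sequence name.
#' @return Invisibly, the number of lines written.
#' @export
write_truth_paf <- function(truth, path, genome_length,
                            ref_name = "sim_genome") {
  matches <- truth$ref_span - truth$n_subs - truth$n_del
  block <- truth$ref_span + truth$n_ins
  lines <- paste(
    truth$read_id, truth$read_length, 0, truth$read_length,
    truth$strand, ref_name, genome_length,
    truth$start - 1, truth$start - 1 + truth$ref_span,
    matches, block, 60,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(length(lines))
}
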