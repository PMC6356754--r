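# shared fixture builders and independent oracles

# tibble of reads from bare base strings
read_tbl <- function(bases, ids = sprintf("r%d", seq_along(bases)),
                     qualities = NA_character_, source = "raw") {
  tibble::tibble(read_id = ids, bases = bases,
                 qualities = qualities, source = source)
}

# random N-free reads, deterministic
random_reads <- function(n, min_len = 3, max_len = 50, seed = 1,
                         alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  bases <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, "")
  read_tbl(bases)
}

# independent naive sliding-window k-mer content oracle
naive_features <- function(bases) {
  nm <- kmer_feature_names()
  out <- stats::setNames(numeric(84), nm)
  for (k in 1:3) {
    n_win <- nchar(bases) - k + 1
    wins <- if (n_win >= 1) {
      vapply(seq_len(n_win), function(i) substr(bases, i, i + k - 1), "")
    } else {
      character()
    }
    wins <- wins[!grepl("N", wins)]
    which_k <- nchar(nm) == k
    if (length(wins) > 0) {
      tab <- table(factor(wins, levels = nm[which_k]))
      out[which_k] <- as.numeric(tab) / length(wins)
    }
  }
  out
}

# wrap a bare matrix + labels as a training set, for direct model tests
make_ts <- function(X, labels, ids = sprintf("t%d", seq_len(nrow(X)))) {
  stopifnot(ncol(X) == 84)
  colnames(X) <- kmer_feature_names()
  feats <- dplyr::bind_cols(
    tibble::tibble(read_id = ids,
                   source = ifelse(labels < 0, "raw", "corrected"),
                   label = labels),
    tibble::as_tibble(X)
  )
  structure(list(features = feats,
                 n_raw = sum(labels == -1),
                 n_corrected = sum(labels == +1)),
            class = "sq_training_set")
}

# normal-equations / generalized-inverse oracle for the linear fit
ginv_weights <- function(X, y) {
  drop(MASS::ginv(t(X) %*% X) %*% t(X) %*% y)
}

# two-pass definitional Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# write a read tibble to a temp file and return the path
tmp_seq_file <- function(reads, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  write_sequences(reads, path)
  path
}

# a small cached benchmark for cross-module tests (not the acceptance one)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(make_benchmark(
        seed = 7, n_raw = 300, n_corrected = 150, genome_length = 30000,
        lq_config = sim_config(n_reads = 300, read_length_mean = 1500,
                               read_length_min = 100, read_length_max = 6000,
                               id_prefix = "raw"),
        hq_config = sim_config(n_reads = 150, read_length_mean = 2500,
                               read_length_min = 2000, read_length_max = 6000,
                               sub_rate = 0.014, ins_rate = 0.008,
                               del_rate = 0.008, error_jitter = c(0.5, 1.5),
                               id_prefix = "corr")
      ))
    }
    cache
  }
})
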