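test_that("information vector hits its closed-form values", {
  freq <- rbind(c(0.25, 0.25, 0.25, 0.25),
                c(1, 0, 0, 0),
                c(0.5, 0.5, 0, 0),
                c(0.25, 0.25, 0.25, 0.25),
                c(0, 0, 0, 1))
  info <- information_vector(freq)
  expect_equal(info[1], 0)
  expect_equal(info[2], log(4))
  expect_equal(info[3], log(2))       # 2 * 0.5 * ln(2)
  expect_equal(info[5], log(4))
  expect_error(information_vector(freq * 2), "sum to 1")
})

test_that("pwm constructor finds the max-information core window", {
  x <- pwm("toy", synthetic_test_pwm())
  expect_equal(nrow(x$freq), 10L)
  expect_equal(x$core_start, 3L)  # positions 3-7 are the conserved block
  expect_equal(rowSums(x$freq), rep(1, 10))
  # count matrix converted to frequencies
  counts <- matrix(c(8, 1, 1, 0), 5, 4, byrow = TRUE)
  xc <- pwm("counts", counts)
  expect_equal(rowSums(xc$freq), rep(1, 5))
  expect_equal(xc$freq[1, 1], 0.8)
  xp <- pwm("counts_pc", counts, pseudocount = 1)
  expect_equal(xp$freq[1, 4], 1 / 14)
})

test_that("similarity is min-max normalized: consensus 1, worst 0", {
  freq <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), 5), 5, 4, byrow = TRUE)
  x <- pwm("flat", freq)
  expect_equal(similarity("AAAAA", x), 1.0)
  expect_equal(similarity("CCCCC", x), 0.0)
  # hand-computed: 4 consensus + 1 worst base; identical info weights
  # cancel, so mss = (4*0.7 + 0.1 - 5*0.1) / (5*0.7 - 5*0.1) = 0.8
  expect_equal(similarity("AAAAC", x), 0.8, tolerance = 1e-12)
  expect_error(similarity("AAAA", x), "window length")
  expect_error(similarity("AANAA", x), "non-ACGT")
  uni <- matrix(0.25, 5, 4)
  expect_error(similarity("AAAAA", pwm("uniform", uni)), "degenerate")
})

test_that("similarity is invariant under consistent base relabeling", {
  set.seed(41)
  freq <- t(apply(matrix(runif(20), 5, 4), 1, function(v) v / sum(v)))
  x <- pwm("rand", freq)
  perm <- c(3, 1, 4, 2)  # A->G, C->A, G->T, T->C
  xp <- pwm("perm", freq[, order(perm)])
  win <- c("A", "C", "G", "T", "A")
  win_p <- DNA_BASES[perm[match(win, DNA_BASES)]]
  expect_equal(similarity(win_p, xp), similarity(win, x), tolerance = 1e-12)
})

test_that("scan finds planted consensus sites and skips N windows", {
  x <- pwm("toy", synthetic_test_pwm())
  consensus <- paste(DNA_BASES[apply(x$freq, 1, which.max)], collapse = "")
  set.seed(14)
  bg <- paste(sample(c("A", "C"), 80, replace = TRUE), collapse = "")
  seqs <- c(s1 = paste0(substr(bg, 1, 30), consensus, substr(bg, 31, 80)))
  hits <- pwm_scan(seqs, x, core_cutoff = 0.95, matrix_cutoff = 0.90)
  perfect <- hits[hits$mss >= 1 - 1e-12, ]
  expect_true(any(perfect$offset == 30 & perfect$strand == "+"))
  expect_equal(perfect$site[perfect$offset == 30 & perfect$strand == "+"],
               consensus)

  all_n <- c(n1 = strrep("N", 60))
  expect_equal(nrow(pwm_scan(all_n, x, 0, 0)), 0L)
  short <- c(tiny = "ACGT")
  expect_equal(nrow(pwm_scan(short, x)), 0L)
  # vacuous cutoffs report every clean window on both strands
  clean <- c(s = strrep("ACGT", 10))
  all_hits <- pwm_scan(clean, x, core_cutoff = 0, matrix_cutoff = 0)
  expect_equal(nrow(all_hits), 2 * (40 - 10 + 1))
})

test_that("hit count is anti-monotone in both cutoffs", {
  x <- pwm("toy", synthetic_test_pwm())
  fx <- make_promoters(x, n = 8, site_rate = 0.5, seed = 19, length = 200)
  grid <- expand.grid(core = c(0, 0.5, 0.8, 0.95, 1),
                      mat = c(0, 0.5, 0.9, 1))
  counts <- mapply(function(cc, mc)
    nrow(pwm_scan(fx$sequences, x, cc, mc)), grid$core, grid$mat)
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$core[j] >= grid$core[i] && grid$mat[j] >= grid$mat[i]) {
        expect_lte(counts[j], counts[i])
      }
    }
  }
})

test_that("reverse-complementing a sequence mirrors hits across strands", {
  x <- pwm("toy", synthetic_test_pwm())
  fx <- make_promoters(x, n = 3, site_rate = 1, seed = 27, length = 120)
  s <- fx$sequences[1]
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  h1 <- pwm_scan(setNames(s, "fwd"), x, 0.7, 0.7)
  h2 <- pwm_scan(setNames(rc, "rev"), x, 0.7, 0.7)
  L <- nrow(x$freq)
  len <- nchar(s)
  mirrored <- data.frame(offset = len - L - h1$offset,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         mss = h1$mss)
  ord <- function(d) d[order(d$offset, d$strand), ]
  expect_equal(ord(mirrored)$offset,
               ord(h2[, c("offset", "strand", "mss")])$offset)
  expect_equal(ord(mirrored)$mss,
               ord(h2[, c("offset", "strand", "mss")])$mss,
               tolerance = 1e-12)
})

test_that("promoter windows are the 500 bp immediately upstream", {
  expect_equal(promoter_window(1000, "+")[c("start", "end")],
               list(start = 499, end = 999))
  expect_equal(promoter_window(100, "+")[c("start", "end")],
               list(start = 0, end = 99))  # clipped at contig start
  expect_equal(promoter_window(1000, "-")[c("start", "end")],
               list(start = 1000, end = 1500))
})

test_that("PWM and FASTA files round-trip", {
  x <- pwm("toy", synthetic_test_pwm())
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwm_file(list(x, pwm("second", matrix(0.25, 6, 4) +
                               c(0.3, -0.1, -0.1, -0.1))), f)
  back <- read_pwm_file(f)
  expect_named(back, c("toy", "second"))
  expect_equal(back$toy$freq, x$freq, tolerance = 1e-12)
  expect_equal(back$toy$core_start, x$core_start)

  skip_if_not_installed("Biostrings")
  fx <- make_promoters(x, n = 4, site_rate = 0.5, seed = 3, length = 80)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(fx$sequences, fa)
  expect_equal(read_fasta(fa), fx$sequences)
})
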