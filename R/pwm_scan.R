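# Promoter scanning for putative transcription-factor binding sites:
# information-weighted matrix/core similarity scoring (the scheme of
# MATCH-style PWM searches) with stringency cutoffs.

#' Construct a position weight matrix
#'
#' Wraps an L x 4 base-frequency matrix (columns A, C, G, T) together
#' with its per-position information vector and the 5-position core
#' window (the 5 consecutive positions with the highest total
#' information, used as a fast, high-stringency pre-filter).
#'
#' @param name matrix name (e.g. a TransFac accession).
#' @param freq numeric L x 4 matrix (L >= 5); rows must sum to 1. If the
#'   rows look like counts (sums != 1) they are converted to frequencies,
#'   adding `pseudocount` to each cell first.
#' @param pseudocount pseudocount for count-to-frequency conversion
#'   (default 0).
#' @return an object of class `"pwm"` with elements `name`, `freq`,
#'   `info` (see [information_vector()]) and `core_start`.
#' @export
pwm <- function(name, freq, pseudocount = 0) {
  stopifnot(is.character(name), length(name) == 1,
            is.matrix(freq), ncol(freq) == 4, nrow(freq) >= 5,
            all(freq >= 0), pseudocount >= 0)
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) {
    freq <- (freq + pseudocount) / (rs + 4 * pseudocount)
  }
  colnames(freq) <- DNA_BASES
  info <- information_vector(freq)
  core_sums <- vapply(seq_len(nrow(freq) - 4L), function(i)
    sum(info[i:(i + 4L)]), numeric(1))
  structure(list(name = name, freq = unname(freq), info = info,
                 core_start = which.max(core_sums)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, core at %d-%d\n",
              x$name, nrow(x$freq), x$core_start, x$core_start + 4L))
  invisible(x)
}

#' Per-position information vector of a frequency matrix
#'
#' `info(i) = sum_b freq(i, b) * ln(4 freq(i, b))` with `0 ln 0 = 0`: 0
#' for a uniform position, `ln 4` for a fully conserved one. Weights each
#' position's contribution to the similarity score by its conservation.
#'
#' @param freq L x 4 base-frequency matrix, rows summing to 1.
#' @return numeric vector of length L, values in \[0, ln 4\].
#' @export
information_vector <- function(freq) {
  stopifnot(is.matrix(freq), ncol(freq) == 4, all(freq >= 0))
  if (any(abs(rowSums(freq) - 1) > 1e-9)) {
    stop("frequency rows must sum to 1", call. = FALSE)
  }
  term <- freq * log(4 * freq)
  term[freq == 0] <- 0
  rowSums(term)
}

# integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

#' Information-weighted similarity of a sequence window to a PWM
#'
#' `S = sum_{i in positions} info(i) * freq(i, base_i)`, min-max
#' normalized to \[0, 1\] using the per-position best and worst base over
#' the same positions: 1 for the consensus, 0 for the per-position worst
#' sequence. With `positions` = the core window this is the core
#' similarity (CSS); over all positions it is the matrix similarity
#' (MSS).
#'
#' @param window character string (or base vector) of length `L`.
#' @param x a [pwm()].
#' @param positions positions to score (default all).
#' @return similarity in \[0, 1\].
#' @export
similarity <- function(window, x, positions = seq_len(nrow(x$freq))) {
  stopifnot(inherits(x, "pwm"))
  b <- if (length(window) == 1L) encode_dna(window) else
    match(toupper(window), DNA_BASES)
  if (length(b) != nrow(x$freq)) {
    stop("window length must equal the matrix length", call. = FALSE)
  }
  if (anyNA(b[positions])) {
    stop("window contains non-ACGT bases at scored positions", call. = FALSE)
  }
  w <- x$info[positions]
  f <- x$freq[positions, , drop = FALSE]
  s <- sum(w * f[cbind(seq_along(positions), b[positions])])
  smin <- sum(w * apply(f, 1, min))
  smax <- sum(w * apply(f, 1, max))
  if (smax - smin <= 0) {
    stop("degenerate matrix: max and min scores coincide", call. = FALSE)
  }
  (s - smin) / (smax - smin)
}

reverse_complement <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

# score every window of one encoded sequence against a pwm; returns
# data.frame(offset0 (0-based in the scanned orientation), css, mss, keep)
scan_one_strand <- function(enc, x, core_cutoff, matrix_cutoff) {
  L <- nrow(x$freq)
  nw <- length(enc) - L + 1L
  if (nw < 1L) return(NULL)
  starts <- seq_len(nw)
  core <- x$core_start:(x$core_start + 4L)
  w_all <- x$info
  fmin <- apply(x$freq, 1, min)
  fmax <- apply(x$freq, 1, max)
  acc_all <- numeric(nw)
  acc_core <- numeric(nw)
  ok <- rep(TRUE, nw)
  for (i in seq_len(L)) {
    bi <- enc[starts + i - 1L]
    ok <- ok & !is.na(bi)
    fi <- x$freq[i, ifelse(is.na(bi), 1L, bi)]
    contrib <- w_all[i] * fi
    acc_all <- acc_all + contrib
    if (i %in% core) acc_core <- acc_core + contrib
  }
  if (!any(ok)) return(NULL)
  mn_all <- sum(w_all * fmin); mx_all <- sum(w_all * fmax)
  mn_core <- sum(w_all[core] * fmin[core])
  mx_core <- sum(w_all[core] * fmax[core])
  if (mx_all - mn_all <= 0 || mx_core - mn_core <= 0) {
    stop("degenerate matrix: max and min scores coincide", call. = FALSE)
  }
  css <- (acc_core - mn_core) / (mx_core - mn_core)
  mss <- (acc_all - mn_all) / (mx_all - mn_all)
  keep <- ok & css >= core_cutoff & mss >= matrix_cutoff
  if (!any(keep)) return(NULL)
  data.frame(offset0 = starts[keep] - 1L, css = css[keep], mss = mss[keep])
}

#' Scan sequences for PWM hits
#'
#' Scores every window of every sequence (both strands by default)
#' against each PWM. A window is reported iff its core similarity reaches
#' `core_cutoff` (the core acts as a pre-filter) and its matrix
#' similarity reaches `matrix_cutoff`; the defaults (0.95 / 0.90) are
#' high-stringency settings. Windows containing non-ACGT bases (e.g. N)
#' are skipped.
#'
#' @param sequences named character vector of DNA sequences (names are
#'   sequence IDs), e.g. from [read_fasta()].
#' @param pwms a [pwm()] or list of them.
#' @param core_cutoff,matrix_cutoff similarity thresholds in \[0, 1\].
#' @param both_strands also scan the reverse complement (default TRUE)?
#' @return data.frame with columns `sequence_id`, `pwm`, `offset`
#'   (0-based start on the plus strand), `strand` (`"+"`/`"-"`), `css`,
#'   `mss`, `site` (the matched subsequence in scanned orientation);
#'   sorted by sequence, offset, strand.
#' @export
pwm_scan <- function(sequences, pwms, core_cutoff = 0.95,
                     matrix_cutoff = 0.90, both_strands = TRUE) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(all(vapply(pwms, inherits, logical(1), "pwm")),
            is.character(sequences), !is.null(names(sequences)),
            core_cutoff >= 0, core_cutoff <= 1,
            matrix_cutoff >= 0, matrix_cutoff <= 1)
  out <- list()
  for (sid in names(sequences)) {
    seq_p <- sequences[[sid]]
    len <- nchar(seq_p)
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      s <- if (st == "+") seq_p else reverse_complement(seq_p)
      enc <- encode_dna(s)
      for (x in pwms) {
        L <- nrow(x$freq)
        hits <- scan_one_strand(enc, x, core_cutoff, matrix_cutoff)
        if (is.null(hits)) next
        offset <- if (st == "+") hits$offset0 else len - L - hits$offset0
        site <- substring(s, hits$offset0 + 1L, hits$offset0 + L)
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = sid, pwm = x$name, offset = offset, strand = st,
          css = hits$css, mss = hits$mss, site = site,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence_id = character(0), pwm = character(0),
                      offset = integer(0), strand = character(0),
                      css = numeric(0), mss = numeric(0),
                      site = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$offset, res$strand, res$pwm), ]
  rownames(res) <- NULL
  res
}

#' Promoter window upstream of a transcription start site
#'
#' The `upstream` bases immediately 5' of the TSS, as a 0-based half-open
#' interval on the reference (plus) strand. For a minus-strand gene the
#' window lies 3' of the TSS coordinate on the reference and is scanned
#' as its reverse complement.
#'
#' @param tss 1-based TSS position on the reference.
#' @param strand `"+"` or `"-"`.
#' @param upstream window size in bases (default 500).
#' @return list with `start`, `end` (0-based half-open) and `strand`.
#' @examples
#' promoter_window(1000, "+")  # [499, 999)
#' @export
promoter_window <- function(tss, strand, upstream = 500) {
  stopifnot(is.numeric(tss), tss >= 1, strand %in% c("+", "-"),
            upstream >= 1)
  if (strand == "+") {
    list(start = max(0, tss - 1 - upstream), end = tss - 1, strand = "+")
  } else {
    list(start = tss, end = tss + upstream, strand = "-")
  }
}

#' Read / write PWM text files
#'
#' One matrix per block: a header line `>name`, then L lines of 4
#' whitespace-separated counts or frequencies in A C G T column order.
#'
#' @param path file path.
#' @param pseudocount passed to [pwm()] for count matrices.
#' @return `read_pwm_file` returns a named list of [pwm()] objects;
#'   the writer returns `path` invisibly.
#' @export
read_pwm_file <- function(path, pseudocount = 0) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads) || heads[1] != 1L) {
    stop("PWM file must start with a '>name' header", call. = FALSE)
  }
  bounds <- c(heads, length(lines) + 1L)
  pwms <- lapply(seq_along(heads), function(i) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(block, "\\s+"), as.numeric)
    if (any(lengths(rows) != 4) || anyNA(unlist(rows))) {
      stop("matrix '", name, "': each line needs 4 numeric values",
           call. = FALSE)
    }
    pwm(name, do.call(rbind, rows), pseudocount = pseudocount)
  })
  stats::setNames(pwms, vapply(pwms, `[[`, character(1), "name"))
}

#' @rdname read_pwm_file
#' @param pwms list of [pwm()] objects.
#' @export
write_pwm_file <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (x in pwms) {
    writeLines(paste0(">", x$name), con)
    writeLines(apply(x$freq, 1, function(v)
      paste(sprintf("%.17g", v), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Thin wrappers around Biostrings returning plain named character
#' vectors, the representation [pwm_scan()] consumes.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences;
#'   the writer returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta requires the 'Biostrings' package", call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("write_fasta requires the 'Biostrings' package", call. = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}
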