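# NNK-library enrichment analysis: per-randomized-position amino-acid
# frequencies per screening round and round-over-round enrichment ratios.
# Reads are fixed-length amplicons covering the randomized stretch, so
# short-read alignment is replaced by position-based codon extraction behind
# a 90% identity gate on the non-randomized bases.

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Describe an NNK library design
#'
#' @param template DNA template of the analyzed amplicon window (A/C/G/T,
#'   length divisible by 3).
#' @param randomized_codons unique 1-based codon indices of the randomized
#'   positions, within the template reading frame.
#' @param rounds optional ordered character vector of screening-round labels.
#' @return a `library_design`.
#' @export
library_design <- function(template, randomized_codons, rounds = NULL) {
  template <- toupper(template)
  if (nchar(template) %% 3 != 0) {
    stop_badarg("template length must be divisible by 3")
  }
  if (grepl("[^ACGT]", template)) {
    stop_badarg("template may only contain A/C/G/T")
  }
  n_codons <- nchar(template) / 3
  randomized_codons <- as.integer(randomized_codons)
  if (any(randomized_codons < 1 | randomized_codons > n_codons)) {
    stop_badarg("randomized codon index out of range (1..", n_codons, ")")
  }
  if (anyDuplicated(randomized_codons)) {
    stop_badarg("randomized codon indices must be unique")
  }
  structure(list(template = template,
                 randomized_codons = sort(randomized_codons),
                 rounds = rounds),
            class = "library_design")
}

# 1-based base positions covered by the randomized codons
.randomized_bases <- function(design) {
  as.vector(vapply(design$randomized_codons,
                   function(p) (p - 1L) * 3L + 1:3, integer(3)))
}

#' Extract the randomized codons from reads
#'
#' A read is usable when its length equals the template length and it matches
#' the template at `min_identity` (default 90%) of the non-randomized bases;
#' a read with an ambiguous base (N) inside a randomized codon is discarded
#' with reason `"ambiguous"`. Vectorized over reads.
#'
#' @param reads character vector of read sequences (or a data frame with a
#'   `seq` column as returned by [read_reads]).
#' @param design a [library_design].
#' @param min_identity required identity over non-randomized bases.
#' @return list with `codons` (matrix: usable reads x randomized positions),
#'   `used` (logical per read) and `discard_reason` (`NA`, `"length"`,
#'   `"identity"` or `"ambiguous"` per read).
#' @export
extract_variable_codons <- function(reads, design, min_identity = 0.9) {
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- toupper(reads)
  n <- length(reads)
  tpl_len <- nchar(design$template)
  reason <- rep(NA_character_, n)

  len_ok <- nchar(reads) == tpl_len
  reason[!len_ok] <- "length"

  rnd <- .randomized_bases(design)
  fixed <- setdiff(seq_len(tpl_len), rnd)
  tpl <- strsplit(design$template, "")[[1]]

  codons <- matrix(NA_character_, nrow = n,
                   ncol = length(design$randomized_codons))
  idx <- which(len_ok)
  if (length(idx) > 0) {
    m <- matrix(unlist(strsplit(reads[idx], ""), use.names = FALSE),
                ncol = tpl_len, byrow = TRUE)
    ident <- rowMeans(m[, fixed, drop = FALSE] ==
                        matrix(tpl[fixed], nrow = length(idx),
                               ncol = length(fixed), byrow = TRUE))
    low <- ident < min_identity
    reason[idx[low]] <- "identity"
    for (j in seq_along(design$randomized_codons)) {
      cstart <- (design$randomized_codons[j] - 1L) * 3L + 1L
      codons[idx, j] <- paste0(m[, cstart], m[, cstart + 1L], m[, cstart + 2L])
    }
    amb <- rowSums(matrix(!(codons[idx, , drop = FALSE] %in%
                              names(Biostrings::GENETIC_CODE)),
                          nrow = length(idx))) > 0
    reason[idx[amb & !low]] <- "ambiguous"
  }
  used <- is.na(reason)
  list(codons = codons[used, , drop = FALSE], used = used,
       discard_reason = reason)
}

#' Per-position amino-acid frequencies of an NNK library round
#'
#' Usable reads (see [extract_variable_codons]) have their randomized codons
#' translated under the standard genetic code — stop codons are retained as a
#' 21st symbol `*` — and the frequency of each residue at each randomized
#' position is its count divided by the number of usable reads, so
#' frequencies sum to 1 per position.
#'
#' @param reads character vector of sequences or a data frame with `seq`.
#' @param design a [library_design].
#' @param min_identity identity gate passed to [extract_variable_codons].
#' @return an `enrichment_table`: `freq` (matrix positions x 21 symbols),
#'   `counts` (`total`, `used`, `discarded`), `discard_reasons` (table).
#' @export
aa_frequencies <- function(reads, design, min_identity = 0.9) {
  ex <- extract_variable_codons(reads, design, min_identity)
  n_used <- nrow(ex$codons)
  if (n_used == 0) stop_badarg("no usable reads")
  gc_tab <- Biostrings::GENETIC_CODE
  freq <- t(vapply(seq_len(ncol(ex$codons)), function(j) {
    aa <- unname(gc_tab[ex$codons[, j]])
    tab <- table(factor(aa, levels = AA_SYMBOLS))
    as.numeric(tab) / n_used
  }, numeric(length(AA_SYMBOLS))))
  dimnames(freq) <- list(
    position = as.character(design$randomized_codons),
    aa = AA_SYMBOLS)
  total <- length(ex$used)
  structure(list(freq = freq,
                 counts = c(total = total, used = sum(ex$used),
                            discarded = total - sum(ex$used)),
                 discard_reasons = table(ex$discard_reason),
                 design = design),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table: %d randomized positions, %d/%d reads used>\n",
              nrow(x$freq), x$counts["used"], x$counts["total"]))
  print(round(x$freq, 3))
  invisible(x)
}

#' Round-over-round enrichment ratios
#'
#' For each randomized position and residue, the pseudo-count-regularized
#' frequency ratio of every round against the first:
#' `ratio_r = (freq_r + pseudo) / (freq_1 + pseudo)`. Ratios are computed on
#' frequencies, so they are invariant to sequencing depth.
#'
#' @param tables list of `enrichment_table`s in round order (>= 2); designs
#'   must match.
#' @param pseudo pseudo-count added to both frequencies (default 1e-4).
#' @return long data frame with columns `round`, `position`, `aa`, `freq`,
#'   `ratio` (vs round 1), and attribute `summary` (last/first ratio per
#'   position x residue).
#' @export
enrichment_ratio <- function(tables, pseudo = 1e-4) {
  if (length(tables) < 2) stop_badarg("need >= 2 rounds")
  d1 <- tables[[1]]$design
  for (tb in tables[-1]) {
    if (!identical(tb$design$template, d1$template) ||
        !identical(tb$design$randomized_codons, d1$randomized_codons)) {
      stop_badarg("library designs differ between rounds")
    }
  }
  rounds <- names(tables) %||% as.character(seq_along(tables))
  if (is.null(names(tables))) names(tables) <- rounds
  f1 <- tables[[1]]$freq
  out <- do.call(rbind, lapply(seq_along(tables), function(r) {
    fr <- tables[[r]]$freq
    data.frame(round = rounds[r],
               position = rep(rownames(fr), times = ncol(fr)),
               aa = rep(colnames(fr), each = nrow(fr)),
               freq = as.vector(fr),
               ratio = as.vector((fr + pseudo) / (f1 + pseudo)),
               stringsAsFactors = FALSE)
  }))
  last <- tables[[length(tables)]]$freq
  attr(out, "summary") <- (last + pseudo) / (f1 + pseudo)
  out
}
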