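SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Read a PoPoolation2 sync file
#'
#' The sync format is tab-separated: chromosome, 1-based position, reference
#' base, then one column per sample of colon-separated counts
#' `A:T:C:G:N:del`. Malformed lines are reported with their line number.
#'
#' @param source path to a sync file, or a character vector of sync lines.
#' @param sample_names optional sample (column) names; defaults to
#'   `S1..Sk`.
#' @return An object of class `sync`: a list with `info` (data.frame of
#'   `chrom`, `pos`, `ref`) and `counts` (an `n_sites x n_samples x 6`
#'   integer array with nucleotide dimension `A,T,C,G,N,del`).
#' @export
#' @examples
#' s <- read_sync(c("sim1\t1000\tA\t10:0:40:0:0:0\t25:0:25:0:0:0"))
#' s$counts[1, 1, "C"]  # 40
read_sync <- function(source, sample_names = NULL) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source)
  } else {
    source
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_sync(sample_names))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 4)) {
    stop(sprintf("sync line %d: expected at least 4 tab-separated columns",
                 which(n_col < 4)[1]))
  }
  if (length(unique(n_col)) != 1) {
    bad <- which(n_col != n_col[1])[1]
    stop(sprintf("sync line %d: inconsistent sample count (%d vs %d)",
                 bad, n_col[bad] - 3L, n_col[1] - 3L))
  }
  n_samples <- n_col[1] - 3L
  mat <- matrix(unlist(fields), ncol = n_col[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos) || any(pos < 1)) {
    stop(sprintf("sync line %d: invalid position", which(is.na(pos) | pos < 1)[1]))
  }
  counts <- array(NA_integer_, dim = c(length(lines), n_samples, 6))
  for (j in seq_len(n_samples)) {
    parts <- strsplit(mat[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6)) {
      stop(sprintf("sync line %d: sample %d has %d count fields, expected 6",
                   which(lengths(parts) != 6)[1], j,
                   lengths(parts)[which(lengths(parts) != 6)[1]]))
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v) || any(v < 0)) {
      bad <- which(vapply(parts, function(p) {
        anyNA(suppressWarnings(as.integer(p))) ||
          any(suppressWarnings(as.integer(p)) < 0, na.rm = TRUE)
      }, logical(1)))[1]
      stop(sprintf("sync line %d: non-integer or negative count in sample %d",
                   bad, j))
    }
    counts[, j, ] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  if (is.null(sample_names)) sample_names <- paste0("S", seq_len(n_samples))
  dimnames(counts) <- list(NULL, sample_names, SYNC_BASES)
  structure(list(
    info = data.frame(chrom = mat[, 1], pos = pos, ref = mat[, 3],
                      stringsAsFactors = FALSE),
    counts = counts
  ), class = "sync")
}

empty_sync <- function(sample_names = NULL) {
  if (is.null(sample_names)) sample_names <- character(0)
  structure(list(
    info = data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), stringsAsFactors = FALSE),
    counts = array(integer(0), dim = c(0, length(sample_names), 6),
                   dimnames = list(NULL, sample_names, SYNC_BASES))
  ), class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites x %d samples\n", n_sites(x),
              dim(x$counts)[2]))
  invisible(x)
}

#' Number of sites in a sync object
#' @param sync a `sync` object.
#' @return Integer count of records.
#' @export
n_sites <- function(sync) nrow(sync$info)

#' Subset a sync object by site index
#' @param sync a `sync` object.
#' @param i integer or logical site index.
#' @return The subset `sync` object.
#' @export
subset_sync <- function(sync, i) {
  structure(list(info = sync$info[i, , drop = FALSE],
                 counts = sync$counts[i, , , drop = FALSE]),
            class = "sync")
}

#' Write a sync object to text
#'
#' Inverse of [read_sync()]: `read_sync(write_sync(x))` is the identity on
#' canonical records.
#'
#' @param sync a `sync` object.
#' @param sink optional path; if `NULL` the lines are returned.
#' @return The sync lines, invisibly when written to a file.
#' @export
write_sync <- function(sync, sink = NULL) {
  if (n_sites(sync) == 0) {
    lines <- character(0)
  } else {
    n_samp <- dim(sync$counts)[2]
    cols <- vapply(seq_len(n_samp), function(j) {
      apply(sync$counts[, j, , drop = FALSE], 1, paste, collapse = ":")
    }, character(n_sites(sync)))
    cols <- matrix(cols, nrow = n_sites(sync))
    lines <- do.call(paste, c(list(sync$info$chrom, sync$info$pos,
                                   sync$info$ref),
                              split(cols, col(cols)), sep = "\t"))
  }
  if (is.null(sink)) return(lines)
  writeLines(lines, sink)
  invisible(lines)
}

#' Build a mask interval set (BED convention)
#'
#' Intervals are 0-based, half-open `[start, end)` per chromosome, merged to
#' canonical non-overlapping form.
#'
#' @param chrom,start,end equal-length vectors of intervals.
#' @return A data.frame of class `mask_set` with merged intervals.
#' @export
mask_set <- function(chrom = character(0), start = integer(0),
                     end = integer(0)) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("mask intervals require start < end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (nrow(df) > 1) {
    df <- df[order(df$chrom, df$start), ]
    merged <- df[1, ]
    for (k in seq_len(nrow(df))[-1]) {
      last <- nrow(merged)
      if (df$chrom[k] == merged$chrom[last] &&
          df$start[k] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], df$end[k])
      } else {
        merged <- rbind(merged, df[k, ])
      }
    }
    df <- merged
    rownames(df) <- NULL
  }
  class(df) <- c("mask_set", "data.frame")
  df
}

#' Read BED intervals into a mask set
#' @param path path to a BED file (chrom, start, end; no header).
#' @return A [mask_set()].
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  mask_set(bed[[1]], bed[[2]], bed[[3]])
}

#' Remove sync records falling in masked intervals
#'
#' Each BED interval is expanded by `flank` bases on both sides (the indel
#' flanking rule); a record at 1-based position `pos` is removed when its
#' 0-based coordinate `pos - 1` falls in any expanded interval on its
#' chromosome. Counts are never altered, only membership. The number of
#' removed records is attached as attribute `n_removed`.
#'
#' @param sync a `sync` object.
#' @param masks a [mask_set()] (empty mask set is the identity).
#' @param flank non-negative integer expansion on each side (default 5).
#' @return The filtered `sync` object.
#' @export
apply_masks <- function(sync, masks, flank = 5) {
  if (nrow(masks) == 0) {
    out <- sync
    attr(out, "n_removed") <- 0L
    return(out)
  }
  p0 <- sync$info$pos - 1L
  drop <- rep(FALSE, n_sites(sync))
  for (k in seq_len(nrow(masks))) {
    drop <- drop | (sync$info$chrom == masks$chrom[k] &
                      p0 >= masks$start[k] - flank &
                      p0 < masks$end[k] + flank)
  }
  out <- subset_sync(sync, !drop)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Call biallelic SNPs from summed counts
#'
#' Counts of the four nucleotides (N and deletions ignored) are summed
#' across all samples; a site is kept iff exactly two alleles reach
#' `min_count`. Sites with three or more qualifying alleles are dropped as
#' multi-allelic rather than reduced to their top two, because the
#' downstream estimator is strictly biallelic and silent reduction would
#' bias frequencies.
#'
#' @param sync a `sync` object.
#' @param min_count minimum summed count per allele (default 5, inclusive).
#' @return A list of class `snp_calls`: `sync` (kept records), `alleles`
#'   (data.frame `chrom`, `pos`, `major`, `minor` by summed count), and
#'   `dropped` (named counts of `monomorphic` and `multiallelic` sites).
#' @export
call_snps <- function(sync, min_count = 5) {
  if (n_sites(sync) == 0) {
    return(structure(list(sync = sync,
                          alleles = data.frame(chrom = character(0),
                                               pos = integer(0),
                                               major = character(0),
                                               minor = character(0)),
                          dropped = c(monomorphic = 0L, multiallelic = 0L)),
                     class = "snp_calls"))
  }
  nuc <- sync$counts[, , 1:4, drop = FALSE]
  tot <- apply(nuc, c(1, 3), sum)  # n_sites x 4
  tot <- matrix(tot, ncol = 4, dimnames = list(NULL, SYNC_BASES[1:4]))
  qualifies <- tot >= min_count
  n_alleles <- rowSums(qualifies)
  keep <- n_alleles == 2
  top2 <- function(i) {
    al <- which(qualifies[i, ])
    al[order(tot[i, al], decreasing = TRUE)][1:2]
  }
  idx <- which(keep)
  pair <- vapply(idx, top2, integer(2))
  alleles <- data.frame(
    chrom = sync$info$chrom[idx],
    pos = sync$info$pos[idx],
    major = SYNC_BASES[pair[1, ]],
    minor = SYNC_BASES[pair[2, ]],
    stringsAsFactors = FALSE
  )
  structure(list(
    sync = subset_sync(sync, keep),
    alleles = alleles,
    dropped = c(monomorphic = sum(n_alleles < 2),
                multiallelic = sum(n_alleles > 2))
  ), class = "snp_calls")
}

#' Per-site, per-sample allele frequencies
#'
#' The frequency of the given allele is its count divided by the total
#' nucleotide count (A+T+C+G; N and deletions excluded from the
#' denominator). A zero denominator yields `NA` (counted in attribute
#' `n_missing`), never an error.
#'
#' @param sync a `sync` object.
#' @param allele character vector (length 1 or `n_sites`) of tracked
#'   alleles, each one of A/T/C/G.
#' @return A list with `freq` and `depth` matrices (`n_sites x n_samples`);
#'   `freq` carries attribute `n_missing`.
#' @export
frequencies <- function(sync, allele) {
  allele <- rep_len(as.character(allele), n_sites(sync))
  if (length(allele) > 0 && !all(allele %in% SYNC_BASES[1:4])) {
    stop("allele must be one of A, T, C, G")
  }
  n <- n_sites(sync)
  n_samp <- dim(sync$counts)[2]
  depth <- matrix(0L, n, n_samp, dimnames = list(NULL, dimnames(sync$counts)[[2]]))
  cnt <- matrix(0L, n, n_samp)
  for (j in seq_len(n_samp)) {
    depth[, j] <- rowSums(sync$counts[, j, 1:4, drop = FALSE])
    if (n > 0) {
      cnt[, j] <- sync$counts[cbind(seq_len(n), j, match(allele, SYNC_BASES))]
    }
  }
  freq <- ifelse(depth > 0, cnt / depth, NA_real_)
  freq <- matrix(freq, n, n_samp, dimnames = dimnames(depth))
  attr(freq, "n_missing") <- sum(depth == 0)
  list(freq = freq, depth = depth)
}
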