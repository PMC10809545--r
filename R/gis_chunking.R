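#' Optimal chunk divisor for a chromosome length and core budget
#'
#' Finds the "fairest" number of pieces to cut a chromosome of `length` bp
#' into, given at most `max_parts` parallel workers: the largest `n` in
#' `[1, max_parts]` that divides `length` exactly, so every chunk has equal
#' size. When no divisor other than 1 exists in range (e.g. a prime length)
#' and `max_parts > 1`, the full budget `max_parts` is used instead and the
#' final chunk of the chromosome absorbs the remainder.
#'
#' @param length Chromosome length in bp (>= 1).
#' @param max_parts Maximum number of chunks, typically the core budget
#'   (>= 1).
#' @return An integer number of parts.
#' @examples
#' optimal_divisor(100, 7)      # 5: the largest divisor of 100 within 7
#' optimal_divisor(43270923, 20) # 19
#' @export
optimal_divisor <- function(length, max_parts) {
  if (length(length) != 1 || is.na(length) || length < 1 ||
      length != trunc(length)) {
    stop("`length` must be a single positive integer", call. = FALSE)
  }
  if (length(max_parts) != 1 || is.na(max_parts) || max_parts < 1 ||
      max_parts != trunc(max_parts)) {
    stop("`max_parts` must be a single positive integer", call. = FALSE)
  }
  candidates <- seq_len(min(max_parts, length))
  divisors <- candidates[length %% candidates == 0]
  best <- max(divisors)
  if (best == 1 && max_parts > 1) {
    return(as.integer(max_parts))
  }
  as.integer(best)
}

#' Derive the uniform chunk length from a genome index
#'
#' Takes the largest chromosome length `L`, picks `n = optimal_divisor(L,
#' max_parts)`, and returns `L / n` (rounded up when `n` does not divide `L`,
#' which only happens through the prime-length fallback). The same chunk
#' length is applied to every chromosome when building the split table.
#'
#' @param index A genome index tibble.
#' @param max_parts Core budget (>= 1).
#' @return Chunk length in bp.
#' @export
chunk_length_for <- function(index, max_parts) {
  big <- largest_chromosome(index)
  n <- optimal_divisor(big$length, max_parts)
  ceiling(big$length / n)
}

#' Build a chromosome split table (CST)
#'
#' Partitions every chromosome of the genome index into consecutive chunks
#' of `chunk_length` bp (1-based inclusive coordinates); the last chunk of a
#' chromosome may be shorter. Chunk numbering restarts at 1 for each
#' chromosome. Either pass a fixed `chunk_length` directly, or pass
#' `max_parts` to derive it from the largest chromosome via
#' [chunk_length_for()].
#'
#' @param index A genome index tibble.
#' @param chunk_length Fixed chunk length in bp (>= 1), or `NULL` to derive
#'   it from `max_parts`.
#' @param max_parts Core budget used when `chunk_length` is `NULL`.
#' @return A tibble of class `cst` with columns `chrom`, `chunk_no`,
#'   `start`, `end` and a `chunk_length` attribute. Per chromosome the
#'   chunks are disjoint and their union is exactly `[1, length]`.
#' @examples
#' idx <- genome_index("Chr01", 11387085)
#' build_cst(idx, chunk_length = 2277417)
#' @export
build_cst <- function(index, chunk_length = NULL, max_parts = NULL) {
  validate_genome_index(index)
  if (is.null(chunk_length)) {
    if (is.null(max_parts)) {
      stop("supply either `chunk_length` or `max_parts`", call. = FALSE)
    }
    chunk_length <- chunk_length_for(index, max_parts)
  }
  if (length(chunk_length) != 1 || is.na(chunk_length) || chunk_length < 1 ||
      chunk_length != trunc(chunk_length)) {
    stop("`chunk_length` must be a single positive integer", call. = FALSE)
  }
  entries <- purrr::map2(index$chrom, index$length, function(chrom, len) {
    n_chunks <- ceiling(len / chunk_length)
    k <- seq_len(n_chunks)
    tibble::tibble(
      chrom = chrom,
      chunk_no = k,
      start = (k - 1) * chunk_length + 1,
      end = pmin(k * chunk_length, len)
    )
  })
  new_cst(dplyr::bind_rows(entries), chunk_length)
}

new_cst <- function(entries, chunk_length) {
  structure(entries,
            chunk_length = chunk_length,
            class = c("cst", class(tibble::tibble())))
}

#' Validate chromosome split table invariants
#'
#' Checks that per chromosome the chunks are numbered 1..k, contiguous
#' (each chunk starts one past the previous end), start at 1, and have
#' uniform length except possibly the final chunk.
#'
#' @param cst A `cst` tibble (columns `chrom`, `chunk_no`, `start`, `end`).
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_cst <- function(cst) {
  need <- c("chrom", "chunk_no", "start", "end")
  if (!all(need %in% names(cst))) {
    stop("a CST needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(cst) == 0) stop("CST is empty", call. = FALSE)
  if (any(cst$start > cst$end)) {
    bad <- which(cst$start > cst$end)[1]
    stop("CST row ", bad, ": start ", cst$start[bad], " > end ",
         cst$end[bad], call. = FALSE)
  }
  uniform_len <- max(cst$end - cst$start + 1)
  for (chrom in unique(cst$chrom)) {
    rows <- cst[cst$chrom == chrom, ]
    if (!identical(as.numeric(rows$chunk_no), as.numeric(seq_len(nrow(rows))))) {
      stop("CST chunks of ", chrom, " are not numbered 1..",
           nrow(rows), call. = FALSE)
    }
    if (rows$start[1] != 1) {
      stop("CST: first chunk of ", chrom, " starts at ", rows$start[1],
           ", expected 1", call. = FALSE)
    }
    if (nrow(rows) > 1) {
      gaps <- rows$start[-1] != rows$end[-nrow(rows)] + 1
      if (any(gaps)) {
        k <- which(gaps)[1] + 1
        stop("CST: chunk ", k, " of ", chrom, " starts at ", rows$start[k],
             ", expected ", rows$end[k - 1] + 1,
             " (gap or overlap)", call. = FALSE)
      }
      lens <- rows$end - rows$start + 1
      if (any(lens[-nrow(rows)] != uniform_len) ||
          lens[nrow(rows)] > uniform_len) {
        stop("CST: chunk lengths of ", chrom,
             " are not uniform (last chunk may only be shorter)",
             call. = FALSE)
      }
    }
  }
  invisible(cst)
}

#' Write a chromosome split table
#'
#' One line per chunk, four whitespace-separated columns:
#' `ChrName Chunk_no Start End`.
#'
#' @param cst A `cst` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cst <- function(cst, path) {
  validate_cst(cst)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(cst$chrom, fmt(cst$chunk_no), fmt(cst$start),
                   fmt(cst$end)), path)
  invisible(path)
}

#' Read a chromosome split table
#'
#' Parses the 4-column text format of [write_cst()], validates all CST
#' invariants (contiguity, numbering, uniform chunk length), and infers the
#' chunk length from the first chunk.
#'
#' @param path Path to a 4-column whitespace-separated file.
#' @return A validated `cst` tibble.
#' @export
read_cst <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("CST file is empty: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    stop("malformed CST line ", bad[1], " in ", path,
         ": expected 4 columns", call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  nums <- suppressWarnings(apply(mat[, 2:4, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = 3)
  if (anyNA(nums)) {
    stop("malformed CST line ", which(rowSums(is.na(nums)) > 0)[1], " in ",
         path, ": non-numeric field", call. = FALSE)
  }
  cst <- new_cst(
    tibble::tibble(chrom = mat[, 1], chunk_no = nums[, 1],
                   start = nums[, 2], end = nums[, 3]),
    chunk_length = max(nums[, 3] - nums[, 2] + 1)
  )
  validate_cst(cst)
  cst
}

#' @export
glance.cst <- function(x, ...) {
  tibble::tibble(
    n_chrom = length(unique(x$chrom)),
    n_chunks = nrow(x),
    chunk_length = attr(x, "chunk_length") %||% (x$end[1] - x$start[1] + 1),
    total_bp = sum(x$end - x$start + 1)
  )
}

#' Plot the chunk layout of a split table
#'
#' Draws one horizontal bar per chromosome, segmented at chunk boundaries.
#'
#' @param object A `cst` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cst <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$chrom <- factor(df$chrom, levels = rev(unique(df$chrom)))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start - 1, xmax = .data$end,
                   ymin = as.integer(.data$chrom) - 0.4,
                   ymax = as.integer(.data$chrom) + 0.4,
                   fill = factor(.data$chunk_no %% 2)),
      colour = "grey30", linewidth = 0.2, show.legend = FALSE) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(df$chrom)),
                                labels = levels(df$chrom)) +
    ggplot2::scale_fill_manual(values = c("grey85", "steelblue")) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Chromosome split table") +
    ggplot2::theme_minimal()
}
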