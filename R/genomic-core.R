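#' Construct a validated table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Strand is one of `"+"`, `"-"`, `"."`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; `0 <= start < end` is enforced.
#' @param strand Strand vector, recycled; defaults to `"."`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, context = "interval") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s validation failed: need 0 <= start < end (first offending row %d: [%s, %s))",
      context, bad[1], format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE)
    ))
  }
  if ("strand" %in% names(x)) {
    bad_s <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad_s) > 0) {
      abort(sprintf("%s validation failed: strand must be one of +, -, . (row %d)",
                    context, bad_s[1]))
    }
  }
  invisible(x)
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 (plus any extra columns, kept as character). Blank lines
#' are skipped; malformed lines raise an error naming the line number.
#'
#' @param path Path to a tab-separated BED file (0-based half-open).
#' @return A tibble with `chrom`, `start`, `end`, and, when present, `name`,
#'   `score`, `strand` and any further columns as `extra1`, `extra2`, ...
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d in %s: expected >= 3 tab-separated fields",
                  keep[bad[1]], path))
  }
  ncol_all <- max(nf)
  mat <- matrix(NA_character_, length(fields), ncol_all)
  for (i in seq_along(fields)) mat[i, seq_len(nf[i])] <- fields[[i]]
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad_num <- which(is.na(start) | is.na(end))
  if (length(bad_num) > 0) {
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                  keep[bad_num[1]], path))
  }
  n_extra <- ncol_all - 3L
  std <- c("name", "score", "strand")
  extra_names <- if (n_extra > 0) {
    c(std[seq_len(min(3, n_extra))],
      if (n_extra > 3) paste0("extra", seq_len(n_extra - 3)))
  } else {
    character()
  }
  out <- tibble(chrom = mat[, 1], start = start, end = end)
  for (j in seq_len(n_extra)) out[[extra_names[j]]] <- mat[, 3L + j]
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  validate_intervals(out, context = sprintf("BED %s", path))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write intervals as a BED file
#'
#' Canonical 3-column BED when only coordinates are present; name/score/strand
#' columns are appended when available. Round-trips `read_bed()` byte-for-byte
#' for 3-column input.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally more).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed input")
  cols <- list(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  for (nm in c("name", "score", "strand")) {
    if (nm %in% names(x)) cols <- c(cols, list(as.character(x[[nm]])))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column chrom/start/end/value bedGraph.
#' @return A signal-track tibble (`chrom`, `start`, `end`, `value`), sorted by
#'   start, guaranteed overlap-free with finite non-negative values.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  value = numeric()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed bedGraph line %d in %s: expected 4 fields",
                  keep[bad[1]], path))
  }
  out <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3))),
    value = suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  )
  validate_track(out, context = sprintf("bedGraph %s", path))
}

#' @keywords internal
validate_track <- function(track, context = "signal track") {
  if (nrow(track) == 0) return(track)
  if (any(is.na(track$value)) || any(!is.finite(track$value))) {
    abort(sprintf("%s: values must be finite", context))
  }
  if (any(track$value < 0)) {
    abort(sprintf("%s: negative signal value", context))
  }
  validate_intervals(track, context)
  track <- arrange(track, .data$chrom, .data$start)
  by_chrom <- split(track, track$chrom)
  for (tr in by_chrom) {
    if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)])) {
      abort(sprintf("%s: overlapping records", context))
    }
  }
  bind_rows(by_chrom)
}

#' Write a signal track as bedGraph
#' @param track Signal-track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

derive_tss_tes <- function(genes) {
  mutate(genes,
         tss = ifelse(.data$strand == "-", .data$end - 1, .data$start),
         tes = ifelse(.data$strand == "-", .data$start, .data$end - 1))
}

#' Read a gene annotation table
#'
#' Expects a TSV with header `gene_id, name, chrom, start, end, strand`.
#' The TSS is the 5' terminus (strand-aware, a single 0-based base) and the
#' TES the 3' terminus; both are derived, never read.
#'
#' @param path Path to the TSV.
#' @return A gene tibble with `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`.
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), name = readr::col_character(),
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), strand = readr::col_character()
  ))
  validate_genes(genes)
}

#' @keywords internal
validate_genes <- function(genes) {
  req <- c("gene_id", "name", "chrom", "start", "end", "strand")
  missing <- setdiff(req, names(genes))
  if (length(missing) > 0) {
    abort(sprintf("gene table missing columns: %s", paste(missing, collapse = ", ")))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id in gene table: %s", dup[1]))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  validate_intervals(genes, "gene table")
  derive_tss_tes(genes)
}

#' Strand-aware window anchored at the TSS
#'
#' For a `+` gene the window is `[tss - upstream, tss + downstream)`; for a
#' `-` gene it is the mirrored `[tss - downstream + 1, tss + upstream + 1)`.
#' Windows are clipped at position 0.
#'
#' @param genes Gene tibble (needs `chrom`, `strand`, `tss`).
#' @param upstream,downstream Non-negative extents in bp.
#' @return Interval tibble with one window per gene plus `gene_id`.
#' @export
tss_window <- function(genes, upstream, downstream) {
  stopifnot(upstream >= 0, downstream >= 0)
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = pmax(0, start), end = pmax(1, end),
         strand = genes$strand)
}

#' Mean signal of a track over query intervals
#'
#' Positions not covered by the track contribute 0. Vectorised over queries
#' via a cumulative-mass lookup.
#'
#' @param track Signal-track tibble on a single chromosome.
#' @param start,end Query interval vectors (0-based half-open).
#' @return Numeric vector of per-interval mean signal.
#' @export
track_mean <- function(track, start, end) {
  stopifnot(length(start) == length(end), all(end > start))
  if (nrow(track) == 0) return(rep(0, length(start)))
  track <- arrange(track, .data$start)
  cum <- c(0, cumsum(track$value * (track$end - track$start)))
  mass_at <- function(x) {
    # cumulative signal mass left of position x
    idx <- findInterval(x, track$start)
    i <- pmax(idx, 1)
    partial <- track$value[i] *
      pmin(pmax(x - track$start[i], 0), track$end[i] - track$start[i])
    ifelse(idx == 0, 0, cum[i] + partial)
  }
  (mass_at(end) - mass_at(start)) / (end - start)
}

#' Re-bin a signal track onto a regular grid
#'
#' Total signal mass (sum of value times width) is preserved.
#'
#' @param track Signal-track tibble on one chromosome.
#' @param bin_bp Grid width in bp.
#' @return A signal-track tibble on the regular grid (zero-mass bins dropped).
#' @export
track_rebin <- function(track, bin_bp) {
  if (nrow(track) == 0) return(track)
  lo <- floor(min(track$start) / bin_bp) * bin_bp
  hi <- ceiling(max(track$end) / bin_bp) * bin_bp
  edges <- seq(lo, hi, by = bin_bp)
  starts <- edges[-length(edges)]
  mean_sig <- track_mean(track, starts, starts + bin_bp)
  out <- tibble(chrom = track$chrom[1], start = starts, end = starts + bin_bp,
                value = mean_sig)
  filter(out, .data$value > 0)
}

#' Read a repeat-element annotation from extended BED
#'
#' Repeats are stored as BED6 plus one extra column: `name` is
#' `class:family` (class SINE or LINE), `score` is the age rank
#' (1 = youngest; `.` when unknown) and column 7 is the element length in bp,
#' which must equal `end - start`.
#'
#' @param path Path to the extended BED file.
#' @return A repeat tibble: `chrom`, `start`, `end`, `repeat_class`, `family`,
#'   `age_rank`, `length_bp`, `strand`.
#' @export
read_repeat_bed <- function(path) {
  raw <- read_bed(path)
  if (!all(c("name", "score", "strand", "extra1") %in% names(raw))) {
    abort("repeat BED needs 7 columns: chrom,start,end,class:family,age_rank,strand,length")
  }
  parts <- strsplit(raw$name, ":", fixed = TRUE)
  out <- tibble(
    chrom = raw$chrom, start = raw$start, end = raw$end,
    repeat_class = vapply(parts, `[`, "", 1),
    family = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    age_rank = suppressWarnings(as.integer(raw$score)),
    length_bp = suppressWarnings(as.numeric(raw$extra1)),
    strand = raw$strand
  )
  if (any(!out$repeat_class %in% c("SINE", "LINE"))) {
    abort("repeat class must be SINE or LINE")
  }
  if (any(out$length_bp != out$end - out$start)) {
    abort("repeat length column disagrees with end - start")
  }
  out
}

#' Write a repeat tibble as extended BED
#' @param repeats Repeat tibble as returned by [read_repeat_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  lines <- sprintf("%s\t%s\t%s\t%s:%s\t%s\t%s\t%s",
                   repeats$chrom,
                   format(repeats$start, scientific = FALSE, trim = TRUE),
                   format(repeats$end, scientific = FALSE, trim = TRUE),
                   repeats$repeat_class, repeats$family,
                   ifelse(is.na(repeats$age_rank), ".", repeats$age_rank),
                   repeats$strand,
                   format(repeats$length_bp, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
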