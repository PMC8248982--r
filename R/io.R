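## Readers and writers for the plain-text formats the pipeline consumes:
## SYNC / TSV allele counts, CSV sample sheets, BED region files, CSV
## recombination maps and GHCND-style daily weather tables. All writers
## emit a leading "## seasonscan <format> <version>" comment line; readers
## skip any number of leading '#' comments.

n_comment_lines <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  n <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

fread_vc <- function(path, ...) {
  data.table::fread(path, skip = n_comment_lines(path), data.table = FALSE, ...)
}

write_vc <- function(df, path, format_tag, sep = ",") {
  writeLines(sprintf("## seasonscan %s v1", format_tag), path)
  data.table::fwrite(df, path, append = TRUE, sep = sep, col.names = TRUE)
}

#' Read pooled allele counts into a `snp_table`
#'
#' Two dialects are supported. `format = "sync"` reads popoolation2-style
#' SYNC: `chrom pos ref` then one `A:T:C:G:N:del` count field per sample.
#' The alternate allele is taken as the highest-count non-reference
#' nucleotide across samples; sites where more than two nucleotides
#' segregate are flagged `multiallelic` for [filter_snps()]. `format =
#' "tsv"` reads the package's own table with `<sample>_ref` / `<sample>_alt`
#' count columns.
#'
#' @param path input file.
#' @param format `"sync"` or `"tsv"`.
#' @param sample_ids sample ids for headerless SYNC files; ignored when the
#'   file carries a `#chrom pos ref id1 id2 ...` header comment.
#' @return a [snp_table()].
#' @export
read_allele_counts <- function(path, format = c("tsv", "sync"), sample_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("read_allele_counts: no such file '%s'", path)
  if (format == "sync") read_sync(path, sample_ids) else read_counts_tsv(path)
}

read_counts_tsv <- function(path) {
  df <- fread_vc(path, sep = "\t")
  if (nrow(df) == 0) {
    warning("read_allele_counts: empty file '", path, "'")
    return(snp_table(data.frame(chrom = character(), pos = integer(),
                                ref_allele = character(), alt_allele = character()),
                     matrix(integer(), 0, 0, dimnames = list(NULL, character())),
                     matrix(integer(), 0, 0, dimnames = list(NULL, character()))))
  }
  fixed <- c("chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(fixed, names(df))
  if (length(miss))
    stop_invalid("read_allele_counts: missing column(s) %s", paste(miss, collapse = ", "))
  refc <- grep("_ref$", setdiff(names(df), fixed), value = TRUE)
  ids <- sub("_ref$", "", refc)
  altc <- paste0(ids, "_alt")
  miss <- setdiff(altc, names(df))
  if (length(miss))
    stop_invalid("read_allele_counts: ref column without matching alt: %s",
                 paste(miss, collapse = ", "))
  rc <- as.matrix(df[, refc, drop = FALSE]); colnames(rc) <- ids
  ac <- as.matrix(df[, altc, drop = FALSE]); colnames(ac) <- ids
  if (any(rc < 0) || any(ac < 0)) {
    bad <- which(rowSums(rc < 0) + rowSums(ac < 0) > 0)[1]
    stop_invalid("read_allele_counts: negative count at data line %d", bad)
  }
  extra <- df[, intersect("multiallelic", names(df)), drop = FALSE]
  snps <- cbind(df[, fixed], extra)
  snp_table(snps, rc, ac)
}

read_sync <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- comments[grepl("^#chrom\\b", comments)]
  if (length(hdr)) {
    flds <- strsplit(sub("^#", "", hdr[1]), "\t")[[1]]
    sample_ids <- flds[-(1:3)]
  }
  if (length(lines) == 0) {
    warning("read_allele_counts: empty SYNC file '", path, "'")
    ids <- sample_ids %||% character()
    return(snp_table(data.frame(chrom = character(), pos = integer(),
                                ref_allele = character(), alt_allele = character()),
                     matrix(integer(), 0, length(ids), dimnames = list(NULL, ids)),
                     matrix(integer(), 0, length(ids), dimnames = list(NULL, ids))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != nf[1]))
    stop_invalid("read_sync: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  ns <- nf[1] - 3L
  if (ns < 1) stop_invalid("read_sync: no sample columns")
  if (is.null(sample_ids)) sample_ids <- sprintf("pool%02d", seq_len(ns))
  if (length(sample_ids) != ns)
    stop_invalid("read_sync: %d sample ids supplied for %d sample columns",
                 length(sample_ids), ns)
  m <- matrix(unlist(parts), ncol = nf[1], byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop_invalid("read_sync: non-integer position at line %d", which(is.na(pos))[1])
  ref <- toupper(m[, 3])
  nuc <- c("A", "T", "C", "G")
  if (!all(ref %in% nuc))
    stop_invalid("read_sync: bad reference allele at line %d", which(!(ref %in% nuc))[1])
  # per-nucleotide counts: SNPs x samples x 4
  cnt <- array(0L, c(length(lines), ns, 4L))
  for (j in seq_len(ns)) {
    sp <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(sp) != 6L))
      stop_invalid("read_sync: malformed count field at line %d", which(lengths(sp) != 6L)[1])
    v <- suppressWarnings(as.integer(unlist(sp)))
    if (anyNA(v))
      stop_invalid("read_sync: non-integer count at line %d",
                   which(rowSums(is.na(matrix(v, ncol = 6, byrow = TRUE))) > 0)[1])
    vm <- matrix(v, ncol = 6, byrow = TRUE)
    cnt[, j, ] <- vm[, 1:4]
  }
  tot <- apply(cnt, c(1, 3), sum)          # SNPs x 4 nucleotide totals
  colnames(tot) <- nuc
  refi <- match(ref, nuc)
  tot_nonref <- tot
  tot_nonref[cbind(seq_along(refi), refi)] <- -1L
  alti <- max.col(tot_nonref, ties.method = "first")
  n_seg <- rowSums(tot > 0)
  multi <- n_seg > 2L
  rc <- cnt[cbind(rep(seq_along(refi), ns), rep(seq_len(ns), each = length(refi)),
                  rep(refi, ns))]
  ac <- cnt[cbind(rep(seq_along(alti), ns), rep(seq_len(ns), each = length(alti)),
                  rep(alti, ns))]
  rc <- matrix(rc, ncol = ns, dimnames = list(NULL, sample_ids))
  ac <- matrix(ac, ncol = ns, dimnames = list(NULL, sample_ids))
  snp_table(data.frame(chrom = chrom, pos = pos, ref_allele = ref,
                       alt_allele = nuc[alti], multiallelic = multi,
                       stringsAsFactors = FALSE),
            rc, ac)
}

#' Write a `snp_table`
#'
#' @param x a `snp_table`.
#' @param path output file.
#' @param format `"tsv"` (round-trips exactly) or `"sync"`.
#' @export
write_allele_counts <- function(x, path, format = c("tsv", "sync")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "snp_table"))
  ids <- sample_ids(x)
  if (format == "tsv") {
    rc <- as.data.frame(x$ref_count); names(rc) <- paste0(ids, "_ref")
    ac <- as.data.frame(x$alt_count); names(ac) <- paste0(ids, "_alt")
    df <- cbind(x$snps[, c("chrom", "pos", "ref_allele", "alt_allele", "multiallelic")],
                rc, ac)
    write_vc(df, path, "allele-counts-tsv", sep = "\t")
  } else {
    nuc <- c("A", "T", "C", "G")
    refi <- match(x$snps$ref_allele, nuc)
    alti <- match(x$snps$alt_allele, nuc)
    cells <- vapply(seq_along(ids), function(j) {
      m <- matrix(0L, n_snps(x), 6L)
      m[cbind(seq_len(n_snps(x)), refi)] <- x$ref_count[, j]
      m[cbind(seq_len(n_snps(x)), alti)] <- x$alt_count[, j]
      apply(m, 1, paste, collapse = ":")
    }, character(n_snps(x)))
    cells <- matrix(cells, nrow = n_snps(x))
    lines <- c(sprintf("## seasonscan sync v1"),
               paste(c("#chrom", "pos", "ref", ids), collapse = "\t"),
               do.call(paste, c(list(x$snps$chrom, x$snps$pos, x$snps$ref_allele),
                                asplit(cells, 2), sep = "\t")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#' @param path CSV file with the [sample_sheet()] columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_invalid("read_sample_sheet: no such file '%s'", path)
  df <- fread_vc(path)
  need <- c("sample_id", "locality", "latitude", "longitude", "season",
            "year", "collection_date", "n_flies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("read_sample_sheet: missing required column(s): %s",
                 paste(miss, collapse = ", "))
  df$season[df$season %in% c("", "NA")] <- NA_character_
  df$collection_date <- as.character(df$collection_date)
  df$collection_date[df$collection_date %in% c("", "NA")] <- NA_character_
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- as_sample_sheet(sheet)
  df <- as.data.frame(sheet)
  df$collection_date <- as.character(df$collection_date)
  write_vc(df, path, "sample-sheet")
  invisible(path)
}

#' Genomic region sets (BED, 0-based half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, BED convention).
#' @param label a name for the set (e.g. `"repeats"`).
#' @return a `region_set`.
#' @export
region_set <- function(intervals, label = "regions") {
  intervals <- as.data.frame(intervals)[, c("chrom", "start", "end")]
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop_invalid("region_set: start must be < end (0-based half-open)")
  if (nrow(intervals) && any(intervals$start < 0))
    stop_invalid("region_set: negative start")
  intervals <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, label = label), class = "region_set")
}

#' @rdname region_set
#' @param path BED file (3+ columns, tab separated).
#' @export
read_regions <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_invalid("read_regions: no such file '%s'", path)
  nc <- n_comment_lines(path)
  first <- readLines(path, n = nc + 1L)
  has_header <- length(first) > nc && grepl("chrom|start", first[nc + 1L])
  df <- data.table::fread(path, skip = nc + has_header, data.table = FALSE,
                          header = FALSE, sep = "\t")
  if (ncol(df) < 3) stop_invalid("read_regions: BED needs >= 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  region_set(df[, 1:3], label = label)
}

#' @rdname region_set
#' @param x a `region_set`.
#' @export
write_regions <- function(x, path) {
  stopifnot(inherits(x, "region_set"))
  writeLines(sprintf("## seasonscan bed v1 label=%s", x$label), path)
  data.table::fwrite(x$intervals, path, append = TRUE, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals of a region set
#' @param x a `region_set`.
#' @export
merge_regions <- function(x) {
  iv <- x$intervals
  if (nrow(iv) < 2) return(x)
  out <- lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    keep_start <- d$start[1]; keep_end <- d$end[1]; res <- NULL
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= keep_end) keep_end <- max(keep_end, d$end[i])
      else { res <- rbind(res, data.frame(chrom = d$chrom[1], start = keep_start, end = keep_end))
             keep_start <- d$start[i]; keep_end <- d$end[i] }
    }
    rbind(res, data.frame(chrom = d$chrom[1], start = keep_start, end = keep_end))
  })
  region_set(do.call(rbind, out), label = x$label)
}

#' Which 1-based positions fall inside a region set?
#'
#' @param chrom,pos vectors of 1-based SNP coordinates.
#' @param regions a `region_set` (0-based half-open).
#' @return logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  stopifnot(inherits(regions, "region_set"))
  regions <- merge_regions(regions)
  iv <- regions$intervals
  out <- logical(length(pos))
  if (nrow(iv) == 0) return(out)
  pos0 <- pos - 1L                    # convert once: 1-based SNP -> 0-based
  for (ch in unique(iv$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    d <- iv[iv$chrom == ch, , drop = FALSE]
    idx <- findInterval(pos0[sel], d$start)
    hit <- idx >= 1 & pos0[sel] < d$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}

#' Recombination-rate map
#'
#' Windows (0-based half-open) tiling each chromosome with a rate in cM/Mb.
#'
#' @param windows data.frame `chrom`, `start`, `end`, `rate`.
#' @export
recomb_map <- function(windows) {
  windows <- as.data.frame(windows)[, c("chrom", "start", "end", "rate")]
  if (any(windows$rate < 0)) stop_invalid("recomb_map: negative rate")
  if (any(windows$start >= windows$end)) stop_invalid("recomb_map: empty window")
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  for (ch in unique(windows$chrom)) {
    d <- windows[windows$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop_invalid("recomb_map: overlapping windows on %s", ch)
  }
  rownames(windows) <- NULL
  structure(list(windows = windows), class = "recomb_map")
}

#' @rdname recomb_map
#' @param path CSV with columns chrom,start,end,rate.
#' @export
read_recomb_map <- function(path) {
  if (!file.exists(path)) stop_invalid("read_recomb_map: no such file '%s'", path)
  df <- fread_vc(path)
  miss <- setdiff(c("chrom", "start", "end", "rate"), names(df))
  if (length(miss))
    stop_invalid("read_recomb_map: missing column(s): %s", paste(miss, collapse = ", "))
  recomb_map(df)
}

#' @rdname recomb_map
#' @param x a `recomb_map`.
#' @export
write_recomb_map <- function(x, path) {
  write_vc(x$windows, path, "recomb-map")
  invisible(path)
}

#' Recombination rate at 1-based positions
#' @param chrom,pos coordinates.
#' @param rmap a `recomb_map`.
#' @return rates in cM/Mb, `NA` outside all windows.
#' @export
recomb_rate_at <- function(chrom, pos, rmap) {
  stopifnot(inherits(rmap, "recomb_map"))
  out <- rep(NA_real_, length(pos))
  pos0 <- pos - 1L
  for (ch in unique(rmap$windows$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    d <- rmap$windows[rmap$windows$chrom == ch, , drop = FALSE]
    idx <- findInterval(pos0[sel], d$start)
    ok <- idx >= 1 & pos0[sel] < d$end[pmax(idx, 1L)]
    val <- rep(NA_real_, sum(sel))
    val[ok] <- d$rate[idx[ok]]
    out[sel] <- val
  }
  out
}

#' Read / write daily weather series (GHCND-style CSV)
#'
#' Columns: `station_id`, `date` (ISO-8601), `tmin_c`, `tmax_c`.
#'
#' @param path CSV file.
#' @return data.frame of daily records with `Date` dates.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop_invalid("read_weather: no such file '%s'", path)
  df <- fread_vc(path)
  miss <- setdiff(c("station_id", "date", "tmin_c", "tmax_c"), names(df))
  if (length(miss))
    stop_invalid("read_weather: missing column(s): %s", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  bad <- !is.na(df$tmin_c) & !is.na(df$tmax_c) & df$tmin_c > df$tmax_c
  if (any(bad))
    stop_invalid("read_weather: tmin > tmax on %s at %s", df$date[bad][1],
                 df$station_id[bad][1])
  df
}

#' @rdname read_weather
#' @param weather daily weather data.frame.
#' @export
write_weather <- function(weather, path) {
  df <- as.data.frame(weather)
  df$date <- as.character(df$date)
  write_vc(df, path, "weather-daily")
  invisible(path)
}
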