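#' Well-level fluorescence/growth time course
#'
#' Container for one plate well: optical density and two fluorescence
#' channels sampled at common times, with a per-point validity mask.
#' Masked-out points are excluded from every downstream computation.
#'
#' @param well_id,strain_id labels.
#' @param times numeric seconds, strictly increasing.
#' @param od,yfp,mcherry numeric series, same length as `times` (>= 4).
#' @param mask logical validity flags; defaults to all `TRUE`.
#' @return An object of class `TimeCourse`.
#' @export
time_course <- function(well_id, strain_id, times, od, yfp, mcherry,
                        mask = NULL) {
  times <- as.numeric(times)
  n <- length(times)
  if (n < 4L) {
    stop_format("well '%s': need at least 4 time points, got %d", well_id, n)
  }
  for (nm in c("od", "yfp", "mcherry")) {
    v <- get(nm)
    if (length(v) != n) {
      stop_format("well '%s': series '%s' has length %d, expected %d",
                  well_id, nm, length(v), n)
    }
  }
  if (any(diff(times) <= 0)) {
    stop_format("well '%s': times must be strictly increasing", well_id)
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  structure(
    list(well_id = as.character(well_id), strain_id = as.character(strain_id),
         times = times, od = as.numeric(od), yfp = as.numeric(yfp),
         mcherry = as.numeric(mcherry), mask = mask),
    class = "TimeCourse"
  )
}

#' @export
print.TimeCourse <- function(x, ...) {
  cat(sprintf("<TimeCourse> well %s (strain %s): %d points over %.1f h, %d masked\n",
              x$well_id, x$strain_id, length(x$times),
              diff(range(x$times)) / 3600, sum(!x$mask)))
  invisible(x)
}

PLATE_ROLES <- c("sample", "media_blank", "yfp_background_strain",
                 "mcherry_background_strain")

#' Load plate-fluorometer time courses
#'
#' Reads a long-format plate table (columns `time`, `well`, `od`, `yfp`,
#' `mcherry`) and splits wells into sample time courses and role-keyed
#' background wells according to a layout.
#'
#' @param path TSV/CSV file with one row per (well, time point).
#' @param layout data.frame with columns `well`, `strain`, `role`; `role`
#'   is one of `"sample"`, `"media_blank"`, `"yfp_background_strain"`
#'   (provides the YFP background curve, i.e. an mCherry-only strain) or
#'   `"mcherry_background_strain"` (a YFP-only strain).
#' @return list with `samples` (named list of [time_course()] objects,
#'   keyed by well) and `backgrounds` (one averaged `TimeCourse` per
#'   background role present).
#' @export
load_plate_timecourses <- function(path, layout) {
  dt <- data.table::fread(path)
  required <- c("time", "well", "od", "yfp", "mcherry")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop_format("plate file '%s' is missing column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  layout <- as.data.frame(layout)
  if (!all(c("well", "strain", "role") %in% names(layout))) {
    stop_format("layout must have columns well, strain, role")
  }
  bad_role <- setdiff(unique(layout$role), PLATE_ROLES)
  if (length(bad_role)) {
    stop_format("unknown layout role(s): %s", paste(bad_role, collapse = ", "))
  }
  wells <- unique(dt$well)
  unknown <- setdiff(wells, layout$well)
  if (length(unknown)) {
    stop_format("well(s) absent from layout: %s", paste(unknown, collapse = ", "))
  }
  tcs <- lapply(wells, function(w) {
    sub <- dt[dt$well == w][order(time)]
    if (anyDuplicated(sub$time)) {
      stop_format("well '%s': duplicated/non-increasing timestamps", w)
    }
    strain <- layout$strain[match(w, layout$well)]
    time_course(w, strain, sub$time, sub$od, sub$yfp, sub$mcherry)
  })
  names(tcs) <- wells
  roles <- layout$role[match(wells, layout$well)]
  backgrounds <- list()
  for (role in setdiff(PLATE_ROLES, "sample")) {
    in_role <- tcs[roles == role]
    if (length(in_role)) backgrounds[[role]] <- average_timecourses(in_role)
  }
  list(samples = tcs[roles == "sample"], backgrounds = backgrounds)
}

# Pointwise mean of replicate wells measured on the same time grid.
average_timecourses <- function(tcs) {
  stopifnot(length(tcs) >= 1L)
  if (length(tcs) == 1L) return(tcs[[1L]])
  t0 <- tcs[[1L]]$times
  for (tc in tcs[-1L]) {
    if (length(tc$times) != length(t0) || any(abs(tc$times - t0) > 1e-6)) {
      stop_format("replicate background wells are on different time grids")
    }
  }
  avg <- function(field) rowMeans(sapply(tcs, `[[`, field))
  time_course(paste(vapply(tcs, `[[`, "", "well_id"), collapse = "+"),
              tcs[[1L]]$strain_id, t0,
              avg("od"), avg("yfp"), avg("mcherry"))
}

#' Write plate time courses to a long-format table
#'
#' Inverse of [load_plate_timecourses()]: one row per (well, time point)
#' with columns `time`, `well`, `od`, `yfp`, `mcherry`. A read-back of the
#' written file reproduces all values exactly.
#'
#' @param tcs list of [time_course()] objects.
#' @param path output TSV path.
#' @export
write_plate_table <- function(tcs, path) {
  if (!length(tcs)) stop_format("no time courses to write")
  # 17 significant digits so that a read-back reproduces every double
  # bit-exactly
  fmt <- function(x) sprintf("%.17g", x)
  rows <- data.table::rbindlist(lapply(tcs, function(tc) {
    data.table::data.table(time = fmt(tc$times), well = tc$well_id,
                           od = fmt(tc$od), yfp = fmt(tc$yfp),
                           mcherry = fmt(tc$mcherry))
  }))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Cloned 3' end construct
#'
#' One cloned 3'-end region: the genomic sequence from the first base after
#' the stop codon (offset 0) up to the next ORF, with the cleavage
#' (polyadenylation) site stored as the 0-based inclusive offset of the
#' last transcribed base when known.
#'
#' @param gene_id systematic gene name.
#' @param sequence DNA string over ACGT (case-insensitive on input, stored
#'   uppercase); at most 1000 bp.
#' @param cleavage_site 0-based offset of the last transcribed base, or
#'   `NA` when unknown.
#' @param orientation `"tandem"`, `"convergent"` or `NA`.
#' @param intergenic_length length of the native intergenic region (bp).
#' @param expression measured expression (a.u. per OD per second), or `NA`.
#' @return An object of class `Construct`.
#' @export
construct <- function(gene_id, sequence, cleavage_site = NA_integer_,
                      orientation = NA_character_,
                      intergenic_length = NA_integer_,
                      expression = NA_real_) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    stop_format("construct '%s': non-ACGT character '%s' at position %d",
                gene_id, substr(sequence, bad, bad), as.integer(bad))
  }
  len <- nchar(sequence)
  if (len > 1000L) {
    stop_format("construct '%s': sequence length %d exceeds 1000 bp", gene_id, len)
  }
  if (!is.na(cleavage_site)) {
    cleavage_site <- as.integer(cleavage_site)
    if (cleavage_site < 0L || cleavage_site >= len) {
      stop_format("construct '%s': cleavage_site %d outside [0, %d)",
                  gene_id, cleavage_site, len)
    }
  }
  if (!is.na(orientation) && !nzchar(orientation)) orientation <- NA_character_
  if (!is.na(orientation) &&
      !orientation %in% c("tandem", "convergent")) {
    stop_format("construct '%s': orientation must be tandem or convergent", gene_id)
  }
  structure(
    list(gene_id = as.character(gene_id), sequence = sequence, utr_start = 0L,
         cleavage_site = cleavage_site, orientation = orientation,
         intergenic_length = intergenic_length,
         expression = as.numeric(expression)),
    class = "Construct"
  )
}

#' @export
print.Construct <- function(x, ...) {
  cat(sprintf("<Construct> %s: %d bp, cleavage site %s, expression %s\n",
              x$gene_id, nchar(x$sequence),
              ifelse(is.na(x$cleavage_site), "unknown", x$cleavage_site),
              ifelse(is.na(x$expression), "NA", format(x$expression, digits = 4))))
  invisible(x)
}

#' Flatten a construct list to a data.frame
#'
#' @param constructs list of [construct()] objects.
#' @return data.frame with one row per construct (sequence included).
#' @export
construct_table <- function(constructs) {
  data.frame(
    gene_id = vapply(constructs, `[[`, "", "gene_id"),
    length = vapply(constructs, function(x) nchar(x$sequence), 0L),
    cleavage_site = vapply(constructs, function(x) as.integer(x$cleavage_site %||% NA), 0L),
    orientation = vapply(constructs, function(x) as.character(x$orientation), ""),
    intergenic_length = vapply(constructs, function(x) as.integer(x$intergenic_length), 0L),
    expression = vapply(constructs, function(x) as.numeric(x$expression), 0),
    sequence = vapply(constructs, `[[`, "", "sequence"),
    stringsAsFactors = FALSE
  )
}

#' Load a construct library from FASTA + annotation table
#'
#' The annotation mirrors the layout of a per-strain expression table:
#' one row per construct with the systematic gene name, measured
#' expression, and optionally the cleavage site, orientation class and
#' intergenic length.
#'
#' @param fasta FASTA file of cloned sequences (ids = gene ids).
#' @param annot TSV with column `gene_id` plus optional `expression`,
#'   `cleavage_site`, `orientation`, `intergenic_length`. Every FASTA id
#'   must appear here.
#' @param expression_scale `"linear"` (default) or `"log"`; recorded as an
#'   attribute on the returned list so downstream analyses know which was
#'   loaded. Log values are not transformed.
#' @return list of [construct()] objects with attribute
#'   `expression_scale`.
#' @export
load_construct_library <- function(fasta, annot,
                                   expression_scale = c("linear", "log")) {
  expression_scale <- match.arg(expression_scale)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- data.table::fread(annot)
  if (!"gene_id" %in% names(ann)) {
    stop_format("annotation '%s' is missing column: gene_id", annot)
  }
  orphans <- setdiff(ids, ann$gene_id)
  if (length(orphans)) {
    stop_format("FASTA id(s) absent from annotation: %s",
                paste(orphans, collapse = ", "))
  }
  get_col <- function(row, col, default) {
    if (col %in% names(ann)) ann[[col]][row] else default
  }
  out <- lapply(seq_along(seqs), function(i) {
    row <- match(ids[i], ann$gene_id)
    construct(
      gene_id = ids[i],
      sequence = as.character(seqs[[i]]),
      cleavage_site = get_col(row, "cleavage_site", NA_integer_),
      orientation = get_col(row, "orientation", NA_character_),
      intergenic_length = get_col(row, "intergenic_length", NA_integer_),
      expression = get_col(row, "expression", NA_real_)
    )
  })
  names(out) <- ids
  attr(out, "expression_scale") <- expression_scale
  out
}

#' Write a construct library as FASTA + annotation table
#'
#' @param constructs list of [construct()] objects.
#' @param fasta,annot output paths.
#' @export
write_construct_library <- function(constructs, fasta, annot) {
  if (!length(constructs)) stop_format("no constructs to write")
  seqs <- Biostrings::DNAStringSet(vapply(constructs, `[[`, "", "sequence"))
  names(seqs) <- vapply(constructs, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- construct_table(constructs)
  data.table::fwrite(tab[setdiff(names(tab), c("sequence", "length"))],
                     annot, sep = "\t")
  invisible(list(fasta = fasta, annot = annot))
}

#' Write cleavage profiles as a BED-like table
#'
#' One row per (gene, position): `gene_id`, `position` (0-based offset
#' from the first base after the stop codon; the inclusive offset of the
#' last transcribed base), `read_count`, `is_main_site`. Rows are sorted
#' by gene then position; a read-back reproduces all counts exactly.
#'
#' @param profiles nonempty list of [cleavage_profile()] objects.
#' @param path output TSV path.
#' @export
write_cleavage_table <- function(profiles, path) {
  if (!length(profiles)) stop_format("no cleavage profiles to write")
  rows <- data.table::rbindlist(lapply(profiles, function(p) {
    pos <- as.integer(names(p$counts))
    data.table::data.table(gene_id = p$gene_id, position = pos,
                           read_count = as.integer(p$counts),
                           is_main_site = pos == p$main_site)
  }))
  data.table::setorder(rows, gene_id, position)
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Read a cleavage table written by [write_cleavage_table()]
#'
#' @param path TSV path.
#' @param depth_threshold strict read-depth threshold used to recompute
#'   the `passes_depth` flag (default 1000; a gene passes only with
#'   strictly more reads).
#' @return list of [cleavage_profile()] objects keyed by gene.
#' @export
read_cleavage_table <- function(path, depth_threshold = 1000L) {
  dt <- data.table::fread(path)
  required <- c("gene_id", "position", "read_count", "is_main_site")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop_format("cleavage table '%s' is missing column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  genes <- unique(dt$gene_id)
  out <- lapply(genes, function(g) {
    sub <- dt[dt$gene_id == g]
    counts <- setNames(as.integer(sub$read_count), sub$position)
    cleavage_profile(g, counts, depth_threshold = depth_threshold)
  })
  names(out) <- genes
  out
}
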