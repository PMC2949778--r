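#' Construct a cohort dataset
#'
#' A cohort is one row per mother: a unique subject id, the group label
#' (`"MDS"` for mothers of Down-syndrome children, `"control"` otherwise),
#' the BNMN frequency (micronucleated binucleated cells per 1000 binucleated
#' lymphocytes) and one genotype call per locus.
#'
#' @param df Data frame with columns `subject_id`, `group`, `bnmn` and one
#'   column per locus named after the locus.
#' @param loci Named list of [locus_schema()] objects (defaults to the seven
#'   canonical folate-pathway loci).
#' @return A `cohort` object (a validated data frame with a `loci` attribute).
#' @export
cohort <- function(df, loci = canonical_loci()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "bnmn", names(loci))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, required, drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$subject_id))
    stop("subject ids must be unique")
  if (!all(df$group %in% c("MDS", "control")))
    stop("group labels must be 'MDS' or 'control'")
  df$bnmn <- as.numeric(df$bnmn)
  if (anyNA(df$bnmn) || any(df$bnmn < 0))
    stop("bnmn must be nonnegative and non-missing")
  for (nm in names(loci)) {
    bad <- !(df[[nm]] %in% loci[[nm]]$labels)
    if (any(bad))
      stop("locus '", nm, "': unknown genotype label(s) ",
           paste(unique(df[[nm]][bad]), collapse = ", "),
           " at row(s) ", paste(which(bad), collapse = ", "))
  }
  structure(df, loci = loci, class = c("cohort", "data.frame"))
}

cohort_loci <- function(ds) attr(ds, "loci", exact = TRUE)

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x), " subjects (",
      sum(x$group == "MDS"), " MDS / ", sum(x$group == "control"),
      " control), ", length(cohort_loci(x)), " loci\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects a header row naming the group, BNMN and locus columns; the mapping
#' from file column names to canonical names is configurable through
#' `col_map`, to absorb alternative header spellings. Both decimal point and
#' decimal comma are accepted for BNMN. A missing `subject_id` column is
#' replaced by row numbers.
#'
#' @param path CSV file path.
#' @param loci Named list of [locus_schema()] objects expected in the file.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`subject_id`, `group`, `bnmn`, locus names) to the file's
#'   column names, e.g. `c(bnmn = "BNMN permille")`.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, loci = canonical_loci(), col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  canon <- c("subject_id", "group", "bnmn", names(loci))
  map <- setNames(canon, canon)
  if (!is.null(col_map)) map[names(col_map)] <- unname(col_map)
  for (nm in setdiff(canon, "subject_id")) {
    if (!map[[nm]] %in% names(raw))
      stop("missing column '", map[[nm]], "' (for '", nm, "') in ", path)
  }
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   subject_id = if (map[["subject_id"]] %in% names(raw))
                     raw[[map[["subject_id"]]]] else as.character(seq_len(nrow(raw))))
  df$group <- raw[[map[["group"]]]]
  bnmn_chr <- sub(",", ".", raw[[map[["bnmn"]]]], fixed = TRUE)
  bnmn <- suppressWarnings(as.numeric(bnmn_chr))
  if (anyNA(bnmn))
    stop("unparseable BNMN value(s) at data line(s) ",
         paste(which(is.na(bnmn)), collapse = ", "), " of ", path)
  df$bnmn <- bnmn
  for (nm in names(loci)) df[[nm]] <- raw[[map[[nm]]]]
  cohort(df, loci)
}

#' Write a cohort to CSV
#'
#' BNMN is printed with 17 significant digits so that a write/read round trip
#' is exact.
#'
#' @param ds A [cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path) {
  out <- as.data.frame(ds)
  out$bnmn <- sprintf("%.17g", out$bnmn)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-group cohort summary
#'
#' Group sizes, per-locus genotype-class counts and the BNMN mean and sample
#' standard deviation (n-1 denominator) per group.
#'
#' @param ds A [cohort()]; both groups must be non-empty.
#' @return A `cohort_summary`: list with `n`, `bnmn_mean`, `bnmn_sd`,
#'   `bnmn_sd_flag` (TRUE where a group has a single record and the SD is
#'   reported as 0) — each a named vector over groups — and `counts`, a list
#'   of 2 x 3 matrices (groups x genotype classes) per locus.
#' @export
summarize_cohort <- function(ds) {
  loci <- cohort_loci(ds)
  groups <- c("MDS", "control")
  n <- vapply(groups, function(g) sum(ds$group == g), integer(1))
  if (any(n == 0L)) stop("both groups must be non-empty")
  bnmn_mean <- vapply(groups, function(g) mean(ds$bnmn[ds$group == g]), numeric(1))
  bnmn_sd <- vapply(groups, function(g) {
    x <- ds$bnmn[ds$group == g]
    if (length(x) < 2L) 0 else sd(x)
  }, numeric(1))
  counts <- lapply(loci, function(sc) {
    m <- t(vapply(groups, function(g) {
      calls <- ds[[sc$name]][ds$group == g]
      vapply(sc$labels, function(l) sum(calls == l), integer(1))
    }, integer(3)))
    dimnames(m) <- list(groups, sc$labels)
    m
  })
  structure(list(n = n, bnmn_mean = bnmn_mean, bnmn_sd = bnmn_sd,
                 bnmn_sd_flag = n < 2L, counts = counts, loci = loci),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>  MDS n =", x$n[["MDS"]], " control n =",
      x$n[["control"]], "\n")
  cat(sprintf("BNMN permille (mean +/- SD): %.1f +/- %.1f vs %.1f +/- %.1f\n",
              x$bnmn_mean[["MDS"]], x$bnmn_sd[["MDS"]],
              x$bnmn_mean[["control"]], x$bnmn_sd[["control"]]))
  for (nm in names(x$counts)) {
    cat(nm, ":\n", sep = "")
    print(x$counts[[nm]])
  }
  invisible(x)
}

# Published per-group genotype counts and BNMN moments for the 29 MDS / 32
# control cohort; used to calibrate the synthetic generator and as a fixture.
table1_counts <- function() {
  list(
    MTHFR677  = rbind(MDS = c(5, 19, 5),  control = c(11, 17, 4)),
    MTHFR1298 = rbind(MDS = c(14, 15, 0), control = c(13, 19, 0)),
    MTRR66    = rbind(MDS = c(9, 14, 6),  control = c(12, 14, 6)),
    MTR2756   = rbind(MDS = c(20, 9, 0),  control = c(24, 6, 2)),
    RFC1_80   = rbind(MDS = c(12, 16, 1), control = c(10, 12, 10)),
    TYMS_28bp = rbind(MDS = c(5, 19, 5),  control = c(6, 14, 12)),
    TYMS_6bp  = rbind(MDS = c(5, 21, 3),  control = c(8, 19, 5))
  )
}

#' Reference cohort summary for the studied population
#'
#' The published per-group distribution of the seven loci (genotype-class
#' counts) and of BNMN (mean 16.5, SD 7.6 per-mille in the 29 MDS mothers;
#' mean 9.3, SD 3.1 in the 32 control mothers), as a `cohort_summary` object
#' usable with [calibrate_from_summary()].
#'
#' @return A `cohort_summary`.
#' @export
reference_summary <- function() {
  loci <- canonical_loci()
  counts <- table1_counts()
  for (nm in names(counts)) dimnames(counts[[nm]]) <-
      list(c("MDS", "control"), loci[[nm]]$labels)
  structure(list(
    n = c(MDS = 29L, control = 32L),
    bnmn_mean = c(MDS = 16.5, control = 9.3),
    bnmn_sd = c(MDS = 7.6, control = 3.1),
    bnmn_sd_flag = c(MDS = FALSE, control = FALSE),
    counts = counts, loci = loci
  ), class = "cohort_summary")
}
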