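#' @include synthetic.R
NULL

# Standard '#' comment header stamped on every output file.
fileHeader <- function(command, seed = NULL) {
  c(sprintf("# irfnet %s", as.character(utils::packageVersion("irfnet"))),
    sprintf("# command: %s", command),
    if (!is.null(seed)) sprintf("# seed: %s",
                                format(seed, scientific = FALSE)))
}

# Read a delimited file, skipping '#' comment lines; tab is the default
# delimiter, comma is auto-detected from the header line.
readDelimBody <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in: ", path)
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  dt <- data.table::fread(text = lines, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  list(table = dt, sep = sep)
}

#' Read a feature matrix
#'
#' Tab- (default, comma auto-detected) separated table with a header row of
#' sample ids and an id column. With `featuresInRows = TRUE` (the layout of
#' gene x genotype matrices) rows are features; the result is always
#' oriented samples x features internally. '#' comment lines are skipped.
#' Missing or non-numeric cells are a hard error naming the offending
#' row/column, unless `imputeMean = TRUE`, which imputes missing values to
#' the feature mean.
#'
#' @param path input file.
#' @param featuresInRows are rows features (default) or samples?
#' @param imputeMean impute missing cells to the feature mean instead of
#'   erroring.
#' @return numeric matrix, samples x features, with dimnames.
#' @export
readMatrix <- function(path, featuresInRows = TRUE, imputeMean = FALSE) {
  body <- readDelimBody(path)$table
  ids <- body[[1]]
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- body[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric value in %s at row '%s', column '%s'",
                   path, ids[bad], names(vals)[j]))
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (featuresInRows) M <- t(M)
  if (anyNA(M)) {
    if (!imputeMean) {
      bad <- which(is.na(M), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value in %s (sample '%s', feature '%s'); use imputeMean = TRUE to impute",
                   path, rownames(M)[bad[1]], colnames(M)[bad[2]]))
    }
    for (j in which(colSums(is.na(M)) > 0)) {
      m <- mean(M[, j], na.rm = TRUE)
      M[is.na(M[, j]), j] <- m
    }
  }
  M
}

#' Write a feature matrix
#'
#' Inverse of [readMatrix()]: tab-separated, id column first, '#' comment
#' header lines recording provenance.
#'
#' @param M numeric matrix, samples x features.
#' @param path output file.
#' @param featuresInRows write features as rows (default).
#' @param comments character vector of '#' header lines (see
#'   [fileHeader()]-style provenance); default records the package version.
#' @export
writeMatrix <- function(M, path, featuresInRows = TRUE,
                        comments = fileHeader("writeMatrix")) {
  stopifnot(is.matrix(M))
  if (is.null(colnames(M))) colnames(M) <- paste0("f", seq_len(ncol(M)))
  if (is.null(rownames(M))) rownames(M) <- paste0("s", seq_len(nrow(M)))
  out <- if (featuresInRows) t(M) else M
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  writeLines(paste(c("id", colnames(out)), collapse = "\t"), con)
  body <- apply(out, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(rownames(out), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a directed weighted edge list
#'
#' Tab-separated `source`, `target`, `weight` with '#' comment headers.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`.
#' @param path file path.
#' @param comments '#' header lines.
#' @return `readEdges` returns the edge data.frame.
#' @export
writeEdges <- function(edges, path, comments = fileHeader("writeEdges")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  writeLines("source\ttarget\tweight", con)
  if (nrow(edges) > 0)
    writeLines(paste(edges$source, edges$target,
                     sprintf("%.17g", edges$weight), sep = "\t"), con)
  invisible(path)
}

#' @rdname writeEdges
#' @export
readEdges <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1 || lines[1] != "source\ttarget\tweight")
    stop("not an edge-list file: ", path)
  lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(source = character(), target = character(),
                      weight = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) stop("malformed edge row in: ", path)
  data.frame(source = vapply(parts, `[`, character(1), 1),
             target = vapply(parts, `[`, character(1), 2),
             weight = as.numeric(vapply(parts, `[`, character(1), 3)))
}

#' Write an importance vector
#'
#' Two-column tab-separated (feature_id, score) with '#' headers.
#'
#' @param imp named numeric vector.
#' @param path output file.
#' @param comments '#' header lines.
#' @export
writeImportance <- function(imp, path, comments = fileHeader("writeImportance")) {
  writeWeights(imp, path, comments = comments)
}

#' Read genotype dosages from a VCF
#'
#' Loads a VCF 4.x file (via \pkg{vcfR}), keeps biallelic records only
#' (multiallelic records are skipped and counted), and maps GT calls to
#' alternate-allele dosages: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, missing
#' -> NA. Phased separators are accepted. SNP ids are CHROM:POS:REF:ALT.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return SNPs x samples dosage matrix with `skipped` (multiallelic record
#'   count) attached as an attribute.
#' @export
readVCFDosage <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT field")
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0", "0")] <- 0
  dosage[clean %in% c("0/1", "1/0")] <- 1
  dosage[clean %in% c("1/1", "1")] <- 2
  dimnames(dosage) <- list(
    paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":"),
    colnames(gt))
  attr(dosage, "skipped") <- skipped
  dosage
}

#' Write a score report
#'
#' Key/value tab-separated summary (observed score, null moments,
#' t-statistic, permutation count, seed); the full null-score vector is
#' written alongside when `nullScoresPath` is given.
#'
#' @param report a [ScoreReport].
#' @param path output file for the summary.
#' @param nullScoresPath optional output file for the null scores.
#' @param comments '#' header lines.
#' @export
writeScoreReport <- function(report, path, nullScoresPath = NULL,
                             comments = fileHeader("writeScoreReport")) {
  stopifnot(is(report, "ScoreReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  kv <- c(intersect_score = report@intersectScore,
          null_mean = report@nullMean,
          null_sd = report@nullSd,
          t_statistic = report@tStatistic,
          n_permutations = report@nPermutations,
          seed = report@seed)
  writeLines(paste(names(kv), sprintf("%.17g", kv), sep = "\t"), con)
  if (!is.null(nullScoresPath)) {
    writeLines(c(comments, sprintf("%.17g", report@nullScores)),
               nullScoresPath)
  }
  invisible(path)
}
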