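## Genotype table IO: two CSV dialects and the Genepop text format.
## Missing code is "0" (zeros in Genepop, per that format's convention).

.metaCols <- c("id", "colony", "site", "caste", "ploidy")

#' Write a genotype table
#'
#' Output is byte-stable for a fixed table: fixed column order, rows in
#' table order, "\\n" line endings, no quoting.  Haploid males are written
#' ploidy-faithfully as a single allele label (never "a/a").
#'
#' @param table a [GenotypeTable-class].
#' @param path output file.
#' @param dialect "csv-wide" (one column per locus, calls "a/b") or
#'   "csv-long" (one row per individual x locus).
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(table, path,
                               dialect = c("csv-wide", "csv-long")) {
  dialect <- match.arg(dialect)
  loci <- lociNames(table)
  ids <- individuals(table)
  info <- indivData(table)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(x) writeLines(x, con, sep = "\n")
  fmtCall <- function(a1, a2, ploidy) {
    if (ploidy == 1L) {
      if (is.na(a1)) "0" else as.character(a1)
    } else {
      if (is.na(a1)) "0/0" else paste0(a1, "/", a2)
    }
  }
  if (dialect == "csv-wide") {
    wline(paste(c(.metaCols, loci), collapse = ","))
    for (i in seq_along(ids)) {
      calls <- vapply(seq_along(loci), function(l)
        fmtCall(table@a1[i, l], table@a2[i, l], info$ploidy[i]),
        character(1))
      wline(paste(c(ids[i], info$colony[i], info$site[i], info$caste[i],
                    info$ploidy[i], calls), collapse = ","))
    }
  } else {
    wline(paste(c(.metaCols, "locus", "allele1", "allele2"),
                collapse = ","))
    for (i in seq_along(ids)) {
      for (l in seq_along(loci)) {
        a1 <- table@a1[i, l]; a2 <- table@a2[i, l]
        a1c <- if (is.na(a1)) "0" else as.character(a1)
        a2c <- if (info$ploidy[i] == 1L || is.na(a2)) "0"
               else as.character(a2)
        wline(paste(c(ids[i], info$colony[i], info$site[i], info$caste[i],
                      info$ploidy[i], loci[l], a1c, a2c), collapse = ","))
      }
    }
  }
  invisible(path)
}

.parseCall <- function(txt, ploidy, id, locus) {
  parts <- strsplit(txt, "/", fixed = TRUE)[[1]]
  if (length(parts) > 2)
    stop(sprintf("format error: %d alleles in one call (individual %s, locus %s)",
                 length(parts), id, locus))
  a <- suppressWarnings(as.integer(parts))
  if (any(is.na(a)))
    stop(sprintf("format error: non-integer allele '%s' (individual %s, locus %s)",
                 txt, id, locus))
  a <- a[a != 0L]  # 0 = missing code
  if (ploidy == 1L) {
    if (length(unique(a)) > 1)
      stop(sprintf("ploidy error: haploid %s heterozygous at locus %s",
                   id, locus))
    if (length(a) == 0) c(NA_integer_, NA_integer_)
    else c(a[1], NA_integer_)
  } else {
    if (length(a) == 0) c(NA_integer_, NA_integer_)
    else if (length(a) == 1 && length(parts) == 1)
      stop(sprintf("format error: diploid single-allele call '%s' (individual %s, locus %s)",
                   txt, id, locus))
    else if (length(a) == 1) c(NA_integer_, NA_integer_)  # e.g. "104/0"
    else sort(a)
  }
}

#' Read a genotype table
#'
#' Individuals typed at fewer than `minLoci` loci are flagged in the
#' returned metadata (`flagged` column), never silently dropped; set
#' `dropFlagged = TRUE` for the hard filter.  Malformed cells raise an
#' error naming the individual and locus.
#'
#' @param path input file.
#' @param dialect "csv-wide", "csv-long" or "genepop".
#' @param minLoci minimum successfully typed loci for inclusion
#'   (default 10, the study's rule for a 12-locus panel).
#' @param dropFlagged remove flagged individuals (default FALSE).
#' @return a [GenotypeTable-class]; `indivData()` carries `typedLoci` and
#'   `flagged`.
#' @export
readGenotypeTable <- function(path,
                              dialect = c("csv-wide", "csv-long", "genepop"),
                              minLoci = 10, dropFlagged = FALSE) {
  dialect <- match.arg(dialect)
  tab <- switch(dialect,
    "csv-wide" = .readCsvWide(path),
    "csv-long" = .readCsvLong(path),
    "genepop"  = readGenepop(path))
  validateGenotypes(tab, minLoci = minLoci, dropFlagged = dropFlagged)
}

.readCsvWide <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  loci <- setdiff(names(df), .metaCols)
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci),
               dimnames = list(df$id, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    pl <- as.integer(df$ploidy[i])
    for (l in seq_along(loci)) {
      call <- .parseCall(df[[loci[l]]][i], pl, df$id[i], loci[l])
      a1[i, l] <- call[1]; a2[i, l] <- call[2]
    }
  }
  info <- data.frame(colony = df$colony, site = df$site, caste = df$caste,
                     ploidy = as.integer(df$ploidy), row.names = df$id,
                     stringsAsFactors = FALSE)
  GenotypeTable(a1, a2, info)
}

.readCsvLong <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  ids <- unique(df$id)
  loci <- unique(df$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  meta <- df[!duplicated(df$id), .metaCols]
  for (r in seq_len(nrow(df))) {
    pl <- as.integer(df$ploidy[r])
    txt <- if (pl == 1L) df$allele1[r]
           else paste0(df$allele1[r], "/", df$allele2[r])
    call <- .parseCall(txt, pl, df$id[r], df$locus[r])
    a1[df$id[r], df$locus[r]] <- call[1]
    a2[df$id[r], df$locus[r]] <- call[2]
  }
  info <- data.frame(colony = meta$colony, site = meta$site,
                     caste = meta$caste, ploidy = as.integer(meta$ploidy),
                     row.names = meta$id, stringsAsFactors = FALSE)
  GenotypeTable(a1, a2, info)
}

#' Validate a genotype table against the minimum-typed-loci rule
#'
#' @param table a [GenotypeTable-class].
#' @param minLoci minimum typed loci (default 10).
#' @param dropFlagged remove failing individuals.
#' @return the table with `typedLoci` and `flagged` metadata columns.
#' @export
validateGenotypes <- function(table, minLoci = 10, dropFlagged = FALSE) {
  typed <- rowSums(!is.na(table@a1))
  info <- indivData(table)
  info$typedLoci <- as.integer(typed)
  info$flagged <- typed < minLoci
  out <- new("GenotypeTable", a1 = table@a1, a2 = table@a2, info = info)
  if (dropFlagged) out <- out[!info$flagged, ]
  out
}

#' Export a genotype table to Genepop format
#'
#' Standard layout: a title line, one locus name per line, one "Pop"
#' block per site, individual lines `id ,  aabbaa bb...` with 2- or
#' 3-digit allele codes chosen to fit the largest label; missing calls
#' are zeros.  Haploid males are encoded as homozygous pseudo-diploids
#' (the convention required by diploid-only downstream tools); the
#' native table keeps true ploidy.
#'
#' @param table a [GenotypeTable-class].
#' @param path output file.
#' @param title title line (default describes the package).
#' @return `path`, invisibly.
#' @export
exportGenepop <- function(table, path, title = "colonykin export") {
  loci <- lociNames(table)
  info <- indivData(table)
  maxAllele <- suppressWarnings(max(table@a1, table@a2, na.rm = TRUE))
  if (!is.finite(maxAllele)) maxAllele <- 0L
  width <- if (maxAllele <= 99) 2L else if (maxAllele <= 999) 3L
           else stop("allele label too large for Genepop 3-digit codes: ",
                     maxAllele)
  code <- function(a) {
    ifelse(is.na(a), strrep("0", width), formatC(a, width = width, flag = "0"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(x) writeLines(x, con, sep = "\n")
  wline(title)
  for (l in loci) wline(l)
  for (s in unique(info$site)) {
    wline("Pop")
    for (i in which(info$site == s)) {
      a1 <- table@a1[i, ]
      a2 <- if (info$ploidy[i] == 1L) a1 else table@a2[i, ]  # pseudo-diploid
      a2[is.na(a1)] <- NA_integer_
      wline(paste0(individuals(table)[i], " ,  ",
                   paste(paste0(code(a1), code(a2)), collapse = " ")))
    }
  }
  invisible(path)
}

#' Read a Genepop file
#'
#' Pop blocks become sites ("pop1", "pop2", ...).  Genepop carries no
#' colony/caste/ploidy metadata: individuals come back as diploid workers
#' with colony = id (haploids exported via the homozygote convention are
#' indistinguishable from homozygous diploids, by design of the format).
#'
#' @param path Genepop file.
#' @return a [GenotypeTable-class].
#' @export
readGenepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop) || firstPop < 3)
    stop("not a Genepop file: need a title, locus names and a Pop line")
  loci <- trimws(lines[2:(firstPop - 1)])
  ## allow comma-separated locus list on one line
  if (length(loci) == 1 && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  ids <- character(); sites <- character(); calls <- list()
  pop <- 0L
  for (i in firstPop:length(lines)) {
    if (isPop[i]) { pop <- pop + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed Genepop individual line: ", lines[i])
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "[[:space:]]+")[[1]]
    if (length(toks) != length(loci))
      stop(sprintf("individual %s: %d genotype fields for %d loci",
                   id, length(toks), length(loci)))
    width <- nchar(toks[1]) / 2
    if (!width %in% c(2, 3))
      stop("Genepop allele codes must be 2 or 3 digits: ", toks[1])
    a1 <- as.integer(substr(toks, 1, width))
    a2 <- as.integer(substr(toks, width + 1, 2 * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    a2[is.na(a1)] <- NA_integer_
    a1[is.na(a2)] <- NA_integer_
    ids <- c(ids, id)
    sites <- c(sites, sprintf("pop%d", pop))
    calls[[length(calls) + 1L]] <- rbind(a1, a2)
  }
  a1 <- do.call(rbind, lapply(calls, function(x) x[1, ]))
  a2 <- do.call(rbind, lapply(calls, function(x) x[2, ]))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  info <- data.frame(colony = ids, site = sites, caste = "worker",
                     ploidy = 2L, row.names = ids, stringsAsFactors = FALSE)
  GenotypeTable(a1, a2, info)
}
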