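#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(x, ...) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x, ...) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("indivData", function(x, ...) standardGeneric("indivData"))
#' @rdname accessors
#' @export
setGeneric("alleleCalls", function(x, ...) standardGeneric("alleleCalls"))
#' @rdname accessors
#' @export
setGeneric("classification", function(x, ...)
  standardGeneric("classification"))
#' @rdname accessors
#' @export
setGeneric("queenGenotype", function(x, ...) standardGeneric("queenGenotype"))
#' @rdname accessors
#' @export
setGeneric("fatherGenotypes", function(x, ...)
  standardGeneric("fatherGenotypes"))
#' @rdname accessors
#' @export
setGeneric("workerAssignments", function(x, ...)
  standardGeneric("workerAssignments"))
#' @rdname accessors
#' @export
setGeneric("freqTables", function(x, ...) standardGeneric("freqTables"))

#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeTable", function(x, ...) rownames(x@a1))

#' @rdname accessors
#' @export
setMethod("lociNames", "GenotypeTable", function(x, ...) colnames(x@a1))

#' @rdname accessors
#' @export
setMethod("indivData", "GenotypeTable", function(x, ...) x@info)

#' @param which "a1" or "a2".
#' @rdname accessors
#' @export
setMethod("alleleCalls", "GenotypeTable", function(x, which = "a1", ...)
  if (which == "a1") x@a1 else x@a2)

#' @rdname accessors
#' @export
setMethod("lociNames", "AlleleFreqs", function(x, ...) names(x@freqs))

#' @rdname accessors
#' @export
setMethod("freqTables", "AlleleFreqs", function(x, ...) x@freqs)

#' @rdname accessors
#' @export
setMethod("classification", "ColonyReconstruction", function(x, ...)
  x@classification)

#' @param queen queen index (1 or 2).
#' @rdname accessors
#' @export
setMethod("queenGenotype", "ColonyReconstruction",
  function(x, queen = 1, ...) x@queens[[queen]]$genotype)

#' @rdname accessors
#' @export
setMethod("fatherGenotypes", "ColonyReconstruction",
  function(x, queen = 1, ...)
    lapply(x@fathers[[queen]], function(f) f$genotype))

#' @rdname accessors
#' @export
setMethod("workerAssignments", "ColonyReconstruction", function(x, ...)
  x@assignment)

#' Subset a GenotypeTable
#'
#' `x[i, j]` subsets individuals (`i`, ids or indices or logical) and loci
#' (`j`).
#'
#' @param x a GenotypeTable.
#' @param i individual selector.
#' @param j locus selector.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@a1))
  if (missing(j)) j <- seq_len(ncol(x@a1))
  new("GenotypeTable",
      a1 = x@a1[i, j, drop = FALSE],
      a2 = x@a2[i, j, drop = FALSE],
      info = x@info[i, , drop = FALSE])
})

#' Combine GenotypeTables row-wise
#'
#' All tables must share the same loci in the same order.
#'
#' @param tables list of GenotypeTable objects.
#' @return a single GenotypeTable.
#' @export
combineGenotypeTables <- function(tables) {
  stopifnot(length(tables) >= 1)
  loci <- lociNames(tables[[1]])
  for (t in tables)
    if (!identical(lociNames(t), loci))
      stop("all tables must share the same loci in the same order")
  a1 <- do.call(rbind, lapply(tables, function(t) t@a1))
  info <- do.call(rbind, c(lapply(tables, function(t) t@info),
                           list(make.row.names = FALSE)))
  rownames(info) <- rownames(a1)
  new("GenotypeTable", a1 = a1,
      a2 = do.call(rbind, lapply(tables, function(t) t@a2)),
      info = info)
}
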