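#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around \code{\link[Biostrings]{readAAStringSet}} that
#' normalizes case, strips whitespace, and validates the alphabet against
#' the 20 standard residues plus X.
#'
#' @param path path to a FASTA file
#' @return a named character vector of uppercase sequences (names from the
#'   FASTA headers)
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(gsub("\\s", "", as.character(ss)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*-]", seqs)
  if (any(bad))
    stop("non-standard residues in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  gsub("[*-]", "", seqs)
}

getBlosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise global protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs \code{gapOpen + gapExtend * L}), computed with
#' \code{\link[Biostrings]{pairwiseAlignment}}. Defaults are BLOSUM62 with
#' gap open 10 and extend 0.5. A simple match/mismatch scheme is available
#' through \code{match}/\code{mismatch} for didactic scoring.
#'
#' @param a,b sequences (character strings) or named length-1 character
#'   vectors (names become sequence ids)
#' @param substitutionMatrix scoring matrix (default BLOSUM62); ignored when
#'   \code{match} is given
#' @param gapOpen,gapExtend affine gap penalties (positive costs)
#' @param match,mismatch optional simple scoring scheme (e.g. +1/-1)
#' @param idA,idB sequence identifiers
#' @return an \linkS4class{AlignmentResult}
#' @examples
#' aln <- globalAlign("GATT", "GAT", match = 1, mismatch = -1,
#'                    gapOpen = 0, gapExtend = 1)
#' aln@score   # 2
#' @export
globalAlign <- function(a, b, substitutionMatrix = NULL, gapOpen = 10,
                        gapExtend = 0.5, match = NULL, mismatch = NULL,
                        idA = NULL, idB = NULL) {
  if (is.null(idA)) idA <- if (!is.null(names(a))) names(a)[1] else "seqA"
  if (is.null(idB)) idB <- if (!is.null(names(b))) names(b)[1] else "seqB"
  a <- toupper(unname(a)); b <- toupper(unname(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (!is.null(match)) {
    alpha <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
    substitutionMatrix <- matrix(mismatch, length(alpha), length(alpha),
                                 dimnames = list(alpha, alpha))
    diag(substitutionMatrix) <- match
  } else if (is.null(substitutionMatrix)) {
    substitutionMatrix <- getBlosum62()
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
  new("AlignmentResult", idA = idA, idB = idB,
      alignedA = as.character(Biostrings::alignedPattern(pa)),
      alignedB = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa))
}

## residue similarity groups used for "similar" highlighting: strong
## substitution classes (hydroxyl, acidic, basic, amide, aliphatic,
## aromatic, small)
similarityGroups <- c("ST", "DE", "KR", "NQ", "ILVM", "FYW", "AG")

residuesSimilar <- function(x, y) {
  if (x == y) return(TRUE)
  any(vapply(similarityGroups, function(g)
    grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), TRUE))
}

#' Percent identity / conservation of a pairwise alignment
#'
#' 100 times the number of qualifying columns over the aligned columns with
#' no gap in either sequence. \code{mode = "identity"} counts identical
#' columns only; \code{mode = "identity_plus_similar"} (the default, matching
#' the black-plus-gray highlighting convention of published alignments) also
#' counts residues from the same similarity group
#' (ST, DE, KR, NQ, ILVM, FYW, AG).
#'
#' @param aln an \linkS4class{AlignmentResult}
#' @param mode "identity_plus_similar" (default) or "identity"
#' @return percentage in [0, 100]; NA with a warning when the alignment has
#'   no ungapped columns
#' @export
conservationPercent <- function(aln,
                                mode = c("identity_plus_similar", "identity")) {
  mode <- match.arg(mode)
  ca <- strsplit(aln@alignedA, "")[[1]]
  cb <- strsplit(aln@alignedB, "")[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) {
    warning("no ungapped columns; conservation undefined")
    return(NA_real_)
  }
  ca <- ca[ok]; cb <- cb[ok]
  hit <- if (mode == "identity") ca == cb
         else mapply(residuesSimilar, ca, cb)
  100 * sum(hit) / sum(ok)
}

## map 1-based positions in the ungapped reference (aligned string refAln)
## to the residues of the query at the same alignment columns
mapReferencePositions <- function(refAln, qryAln, positions) {
  rc <- strsplit(refAln, "")[[1]]
  qc <- strsplit(qryAln, "")[[1]]
  refPos <- cumsum(rc != "-")
  vapply(positions, function(p) {
    col <- which(refPos == p & rc != "-")[1]
    if (is.na(col)) "-" else qc[col]
  }, "")
}

#' Diagnostic residues and Rab6 subfamily call
#'
#' Extracts the query residues aligned to positions 63, 106 and 139 of the
#' Rab6A reference (1-based, ungapped Rab6A numbering) and classifies the
#' query: threonine at 106 with serine at 139 is the Rab6A-like subfamily,
#' serine at 106 with threonine at 139 the Rab6B-like subfamily, anything
#' else (including a gap at a diagnostic column) is ambiguous. Position 63 is
#' reported but does not enter the call: it splits the isoforms differently
#' from the 106/139 pair.
#'
#' @param aln an \linkS4class{AlignmentResult} whose FIRST sequence is the
#'   Rab6A reference and whose second is the query
#' @param positions diagnostic positions in Rab6A numbering (fixed default
#'   c(63, 106, 139))
#' @return list of class \code{DiagnosticProfile}: \code{residues} (named
#'   character vector), \code{subfamily} ("Rab6A-like", "Rab6B-like" or
#'   "ambiguous"), \code{query}
#' @examples
#' seqs <- syntheticRab6Set()
#' aln <- globalAlign(seqs["Rab6A_synthetic"], seqs["RAB-6.1_synthetic"])
#' diagnosticProfile(aln)$subfamily   # "Rab6A-like"
#' @export
diagnosticProfile <- function(aln, positions = c(63L, 106L, 139L)) {
  res <- mapReferencePositions(aln@alignedA, aln@alignedB, positions)
  names(res) <- paste0("pos", positions)
  r106 <- res[["pos106"]]; r139 <- res[["pos139"]]
  subfamily <- if (r106 == "T" && r139 == "S") "Rab6A-like"
               else if (r106 == "S" && r139 == "T") "Rab6B-like"
               else "ambiguous"
  structure(list(residues = res, subfamily = subfamily, query = aln@idB),
            class = "DiagnosticProfile")
}

#' @export
print.DiagnosticProfile <- function(x, ...) {
  cat(sprintf("DiagnosticProfile [%s]: %s -> %s\n", x$query,
              paste(names(x$residues), x$residues, sep = "=",
                    collapse = ", "), x$subfamily))
  invisible(x)
}

## deterministic "dissimilar" substitution: replace a residue with one from a
## different similarity group (never identical, never similar)
dissimilarSub <- function(r) {
  pool <- c("W", "D", "K", "P", "F", "H", "E", "C")
  for (p in pool) if (!residuesSimilar(r, p)) return(p)
  "P"
}

#' Synthetic Rab6-family sequence set
#'
#' A programmatically generated, clearly synthetic stand-in for the seven
#' Rab6-family proteins used in subfamily classification (four human Rab6
#' isoforms, yeast Ypt6, and the two C. elegans proteins RAB-6.1 and
#' RAB-6.2). These are NOT the real database sequences: they are built from a
#' random 200-residue scaffold and encode only the comparative structure the
#' analysis exercises — the diagnostic residues at positions 63/106/139 of
#' each isoform (Rab6A: V/T/S; Rab6A': I/T/S; Rab6B: V/S/T; Rab6C: I/T/S;
#' RAB-6.1: V/T/S; RAB-6.2: I/S/T; Ypt6: I/D/T), exactly three residue
#' differences between Rab6A and Rab6A', and 10% dissimilar divergence
#' between RAB-6.1 and RAB-6.2 (90% conservation). All sequence ids carry a
#' "_synthetic" suffix. For analyses of the real proteins, supply the
#' database sequences through \code{\link{readFastaProteins}}.
#'
#' @param length scaffold length in residues (default 200)
#' @return named character vector of 7 synthetic protein sequences
#' @export
syntheticRab6Set <- function(length = 200L) {
  stopifnot(length >= 150L)
  diagPos <- c(63L, 106L, 139L)
  ## fixed internal seed: the set is a reference fixture, not a simulation
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(6201L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  scaffold <- sample(aa, length, replace = TRUE)
  setDiag <- function(s, r63, r106, r139) {
    s[diagPos] <- c(r63, r106, r139); s
  }
  mutate <- function(s, n, avoid = diagPos) {
    pos <- sample(setdiff(seq_along(s), avoid), n)
    s[pos] <- vapply(s[pos], dissimilarSub, "")
    s
  }
  rab6a <- setDiag(scaffold, "V", "T", "S")
  ## Rab6A' differs from Rab6A at exactly 3 residues, one of them position 63
  rab6ap <- rab6a
  rab6ap[63L] <- "I"
  extra <- sample(setdiff(seq_along(rab6a), diagPos), 2)
  rab6ap[extra] <- vapply(rab6a[extra], dissimilarSub, "")
  rab6b <- setDiag(mutate(rab6a, round(0.08 * length)), "V", "S", "T")
  rab6c <- setDiag(mutate(rab6ap, round(0.03 * length)), "I", "T", "S")
  rab61 <- setDiag(mutate(rab6a, round(0.05 * length)), "V", "T", "S")
  ## RAB-6.2: 10% of positions changed to dissimilar residues (90%
  ## conservation) plus the similar-group diagnostic swaps
  rab62 <- setDiag(mutate(rab61, round(0.10 * length)), "I", "S", "T")
  ypt6 <- setDiag(mutate(rab6a, round(0.20 * length)), "I", "D", "T")
  out <- vapply(list(rab6a, rab6ap, rab6b, rab6c, rab61, rab62, ypt6),
                paste, "", collapse = "")
  names(out) <- paste0(c("Rab6A", "Rab6Aprime", "Rab6B", "Rab6C",
                         "RAB-6.1", "RAB-6.2", "Ypt6"), "_synthetic")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}
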