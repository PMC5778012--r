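#' Locate loci diverging from the telomeric repeat in one read
#'
#' Fragmentary local alignment of a read against the telomeric repeat.
#' The read is segmented into maximal runs that continue the repeat at
#' one of its six phase offsets; runs are matched wholly, abutting runs
#' mark a single indel mismatch at the lower-Phred junction locus,
#' intervening segments of length four or more are Hamming-aligned
#' against all six offsets (ties broken by the lower mean Phred at the
#' mismatches), and shorter intervening segments are marked in full.
#' Reads shorter than one hexamer cannot contain a complete repeat and
#' are marked in full.  N bases never match the repeat.
#'
#' @param seq a single read sequence (character, A/C/G/T/N).
#' @param phred integer vector of per-base Phred scores, same length.
#' @param unit repeat unit to decode against; by default the read's
#'   dominant repeat (\code{TTAGGG} unless \code{CCCTAA} occurs more
#'   often) is used.
#' @return integer 0/1 vector, 1 at each diverging locus.
#' @examples
#' findMismatchingLoci(strrep("TTAGGG", 4), rep(30L, 24))
#' @export
findMismatchingLoci <- function(seq, phred, unit = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L,
            nchar(seq) == length(phred))
  if (is.null(unit)) {
    unit <- if (.count_occurrences_cpp(seq, TELO_C) >
                .count_occurrences_cpp(seq, TELO_G)) TELO_C else TELO_G
  }
  .mismatch_loci_cpp(seq, as.integer(phred), unit)
}

#' Summarise a read's mismatch loci
#'
#' Computes z, the number of mismatching loci, and lambda, the floor of
#' the mean Phred score at those loci offset by the global minimum
#' Phred.  Reads with no mismatches carry no information about error and
#' must be excluded from the joint matrices.
#'
#' @param m integer 0/1 mismatch vector (from [findMismatchingLoci()]).
#' @param phred integer Phred vector of the same length.
#' @param pMin global minimum observed Phred score.
#' @return list with elements \code{z} and \code{lam}.
#' @export
summarizeRead <- function(m, phred, pMin) {
  z <- sum(m)
  if (z == 0L)
    stop("read has no mismatching loci; it contributes to no matrix")
  list(z = as.integer(z),
       lam = as.integer(floor(sum(m * phred) / z) - pMin))
}

# Per-read mismatch statistics for a whole TELBAM, batched through the
# C++ kernel.  Adds columns m, z, pm (Phred sum at mismatches), lam,
# nFwd, nRev to the reads DataFrame.
mismatchStats <- function(reads) {
  if (!is.null(reads$z)) return(reads)
  pMin <- metadata(reads)$pMin
  res <- .mismatch_scan_cpp(reads$seq, as.list(reads$phred), TELO_G, TELO_C)
  reads$m <- IntegerList(res$m)
  reads$z <- res$z
  reads$lam <- ifelse(res$z > 0L,
                      as.integer(floor(res$pm / res$z) - pMin),
                      NA_integer_)
  reads$nFwd <- res$fwd
  reads$nRev <- res$rev
  reads
}

#' Build the joint Phred/mismatch count matrices X and Y
#'
#' X tallies reads by (lambda, z): the floored mean Phred at mismatching
#' loci (rows, offset by the minimum observed Phred) against the number
#' of mismatching loci (columns).  Y is the random-locus analogue: for
#' each read the same number z of loci is drawn uniformly without
#' replacement and the mean Phred over those loci is tallied instead.
#' Reads with z = 0 are excluded (lambda is undefined); reads where every
#' locus mismatches are excluded as well, since the column range runs to
#' L - 1, and their number is reported.
#'
#' @param reads DataFrame from [readTelbam()].
#' @param seed integer seed fixing the random loci drawn for Y.
#' @return list with integer matrices \code{X} and \code{Y} (rows named
#'   by lambda 0..pMax-pMin, columns by z 0..L-1) and the count
#'   \code{dropped}.
#' @export
buildJointMatrices <- function(reads, seed = 1L) {
  reads <- mismatchStats(reads)
  md <- metadata(reads)
  p <- md$pMax - md$pMin
  L <- md$readLength
  dims <- c(p + 1L, max(L, 1L))
  dn <- list(lam = 0:p, z = 0:(dims[2L] - 1L))
  X <- matrix(0L, dims[1L], dims[2L], dimnames = dn)
  Y <- matrix(0L, dims[1L], dims[2L], dimnames = dn)
  widths <- nchar(reads$seq)
  use <- which(reads$z >= 1L & reads$z < widths & reads$z < dims[2L])
  dropped <- sum(reads$z >= 1L) - length(use)
  if (length(use)) {
    xt <- table(factor(reads$lam[use], levels = 0:p),
                factor(reads$z[use], levels = dn$z))
    X <- X + unclass(xt)
    mu <- withSeed(seed, {
      phr <- as.list(reads$phred[use])
      zz <- reads$z[use]
      ww <- widths[use]
      vapply(seq_along(use), function(i) {
        loci <- sample.int(ww[i], zz[i])
        as.integer(floor(sum(phr[[i]][loci]) / zz[i]) - md$pMin)
      }, integer(1))
    })
    yt <- table(factor(mu, levels = 0:p),
                factor(reads$z[use], levels = dn$z))
    Y <- Y + unclass(yt)
  }
  storage.mode(X) <- "integer"
  storage.mode(Y) <- "integer"
  list(X = X, Y = Y, dropped = as.integer(dropped))
}

# Label 4-connected components of a logical matrix; 0 marks background.
connectedComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1L, 2L)
    lab[i0, j0] <- cur
    while (nrow(queue)) {
      i <- queue[1L, 1L]; j <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Build the binary error mask E from the joint matrices
#'
#' Computes D = X - Y and thresholds it at k, the maximum of D over the
#' high-Phred/high-mismatch quadrant (row values above half the Phred
#' range, column values above half the read length), where no genuine
#' error signal is expected.  The raw mask is then denoised by keeping
#' only 4-connected components of two or more cells that touch the
#' low-Phred rows (values up to a quarter of the Phred range), and
#' finally the low-Phred region is filled: every cell in those rows, up
#' to the rightmost denoised column, with positive D is set.  Reads whose
#' (lambda, z) cell is set are treated as complete telomere reads
#' suffering from sequencing error.
#'
#' @param X,Y integer matrices from [buildJointMatrices()].
#' @param seed seed recorded in the profile (provenance only).
#' @param pMin,pMax the global Phred range the rows are offset against.
#' @return an [ErrorProfile-class].
#' @export
buildErrorMask <- function(X, Y, seed = 1L, pMin = 0L,
                           pMax = pMin + nrow(X) - 1L) {
  if (!identical(dim(X), dim(Y)))
    stop("X and Y must have identical dimensions")
  D <- X - Y
  p <- nrow(D) - 1L
  L <- ncol(D)
  rowVals <- 0:p
  colVals <- 0:(L - 1L)
  quadRows <- rowVals > p / 2
  quadCols <- colVals > L / 2
  k <- if (any(quadRows) && any(quadCols))
    max(D[quadRows, quadCols, drop = FALSE]) else 0
  E <- D > k

  # denoise: keep components (>= 2 cells) anchored in the low-Phred rows
  r <- floor(p / 4)
  lowRows <- rowVals <= r
  if (any(E)) {
    lab <- connectedComponents(E)
    keep <- integer(0)
    for (cc in seq_len(max(lab))) {
      cells <- which(lab == cc, arr.ind = TRUE)
      if (nrow(cells) >= 2L && any(lowRows[cells[, 1L]]))
        keep <- c(keep, cc)
    }
    E <- matrix(lab %in% keep, nrow(E), ncol(E))
  }

  # low-Phred capture: fill positive-D cells in rows <= r up to the
  # rightmost column already anchored there
  anchored <- which(apply(E[lowRows, , drop = FALSE], 2L, any))
  if (length(anchored)) {
    jMax <- max(anchored)
    fill <- lowRows & (D > 0) &
      matrix(rep(seq_len(L) <= jMax, each = nrow(D)), nrow(D), L)
    E <- E | fill
  }

  Ei <- matrix(as.integer(E), nrow(D), ncol(D), dimnames = dimnames(X))
  new("ErrorProfile", E = Ei, X = X, Y = Y, D = D, k = as.numeric(k),
      pMin = as.integer(pMin), pMax = as.integer(pMax),
      seed = as.integer(seed), dropped = 0L)
}

#' Build the complete error profile of a TELBAM in one call
#'
#' Convenience wrapper: computes per-read mismatch statistics, the joint
#' matrices X and Y, and the final mask E.
#'
#' @param reads DataFrame from [readTelbam()] (or a path/handle, which is
#'   loaded first).
#' @param seed integer seed for the random loci of Y.
#' @return an [ErrorProfile-class].
#' @export
buildErrorProfile <- function(reads, seed = 1L) {
  if (is.character(reads) || is(reads, "TelbamHandle"))
    reads <- readTelbam(reads)
  md <- metadata(reads)
  jm <- buildJointMatrices(reads, seed = seed)
  prof <- buildErrorMask(jm$X, jm$Y, seed = seed, pMin = md$pMin,
                         pMax = md$pMax)
  prof@dropped <- jm$dropped
  prof
}

#' Write error-profile diagnostics to a directory
#'
#' Dumps the X, Y, D and E matrices as tab-separated text and renders a
#' four-panel heatmap (PNG) of the joint distributions and the final
#' mask, for eyeballing whether the low-Phred error hotspot was
#' captured.
#'
#' @param profile an [ErrorProfile-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
writeErrorProfile <- function(profile, dir, prefix = "profile") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mats <- list(X = profile@X, Y = profile@Y, D = profile@D,
               E = profile@E)
  for (nm in names(mats))
    write.table(mats[[nm]],
                file.path(dir, sprintf("%s_%s.tsv", prefix, nm)),
                sep = "\t", quote = FALSE, col.names = NA)
  grDevices::png(file.path(dir, paste0(prefix, "_heatmap.png")),
                 width = 1200, height = 900)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (nm in names(mats)) {
    m <- mats[[nm]]
    graphics::image(x = as.integer(colnames(m)),
                    y = as.integer(rownames(m)), z = t(m),
                    xlab = "mismatching loci z",
                    ylab = "mean Phred at mismatches (offset)",
                    main = nm, useRaster = TRUE)
  }
  invisible(dir)
}
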