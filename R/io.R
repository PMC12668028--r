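## Plain-text interchange formats: spike event lists, rasters, moment sets,
## model files (bit-exact round trip), thermo curves, and flat key=value
## configuration files.

#' Write / read a spike event list
#'
#' Format: header lines \code{#channels=N}, \code{#timesteps=T} and
#' \code{#dt_ms=<float>} followed by tab-separated
#' \code{timestep<TAB>channel} rows with 0-based channels.  The same
#' reader ingests recording-style event lists whose clock unit is given
#' in milliseconds via \code{dt_ms}.
#'
#' @param events a \linkS4class{SpikeEvents}.
#' @param path file path.
#' @return \code{readSpikeEvents} returns a \linkS4class{SpikeEvents}.
#' @export
writeSpikeEvents <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#channels=", events@nChannels),
               paste0("#timesteps=", format(events@nTimesteps, scientific = FALSE)),
               paste0("#dt_ms=", format(events@dtMs, digits = 17))), con)
  if (length(events@time))
    writeLines(paste(format(events@time, scientific = FALSE, trim = TRUE),
                     events@channel - 1L, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeSpikeEvents
#' @export
readSpikeEvents <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("missing header line #", key, "= in ", path)
    as.numeric(sub(paste0("^#", key, "="), "", hit[1]))
  }
  nCh <- as.integer(getv("channels"))
  nTs <- getv("timesteps")
  dtMs <- suppressWarnings(getv("dt_ms"))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad))
      stop("malformed event row at line ",
           which(!grepl("^#", lines) & nzchar(lines))[bad[1]], " of ", path)
    tm <- as.numeric(vapply(parts, `[`, "", 1))
    ch <- as.integer(vapply(parts, `[`, "", 2)) + 1L
    if (anyNA(tm) || anyNA(ch))
      stop("non-numeric event row in ", path)
    o <- order(tm)
    new("SpikeEvents", time = tm[o], channel = ch[o], nChannels = nCh,
        nTimesteps = nTs, dtMs = dtMs)
  } else {
    new("SpikeEvents", time = numeric(0), channel = integer(0),
        nChannels = nCh, nTimesteps = nTs, dtMs = dtMs)
  }
}

#' Write / read a +/-1 raster
#'
#' Header \code{#channels,#bins,#bin_width}; then one tab-separated row of
#' \eqn{\pm 1} per channel.
#'
#' @param raster a \linkS4class{BinnedRaster}.
#' @param path file path.
#' @export
writeRaster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(raster@sigma), ncol(raster@sigma),
                   format(raster@binWidth, digits = 17), sep = ","), con)
  apply(raster@sigma, 1, function(row)
    writeLines(paste(row, collapse = "\t"), con))
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  sig <- matrix(-1L, hdr[1], hdr[2])
  for (i in seq_len(hdr[1]))
    sig[i, ] <- as.integer(strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]])
  new("BinnedRaster", sigma = sig, binWidth = hdr[3])
}

#' Export / import a moment set in long format
#'
#' Tab-separated columns: kind ("mean", "pair", "pk"), index1, index2,
#' value, se.  Pairs are stored once, lexicographically.
#'
#' @param moments a \linkS4class{MomentSet}.
#' @param path file path.
#' @export
writeMoments <- function(moments, path) {
  n <- length(moments@mean)
  pi <- pairIndices(n)
  df <- rbind(
    data.frame(kind = "mean", index1 = seq_len(n), index2 = NA,
               value = moments@mean, se = moments@se$mean),
    data.frame(kind = "pair", index1 = pi[, 1], index2 = pi[, 2],
               value = moments@pair[pi], se = moments@se$pair[pi]),
    data.frame(kind = "pk", index1 = 0:n, index2 = NA,
               value = moments@pk, se = moments@se$pk))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#channels=", n, "\t#bins=",
                    format(moments@nBins, scientific = FALSE)), con)
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMoments
#' @export
readMoments <- function(path) {
  hdr <- readLines(path, n = 1)
  n <- as.integer(sub("^#channels=(\\d+).*", "\\1", hdr))
  nb <- as.numeric(sub(".*#bins=([0-9eE.+]+).*", "\\1", hdr))
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1)
  m <- df$value[df$kind == "mean"]
  mSe <- df$se[df$kind == "mean"]
  pv <- df[df$kind == "pair", ]
  pair <- matrix(0, n, n)
  pairSe <- matrix(0, n, n)
  pair[cbind(pv$index1, pv$index2)] <- pv$value
  pair <- pair + t(pair); diag(pair) <- 1
  pairSe[cbind(pv$index1, pv$index2)] <- pv$se
  pairSe <- pairSe + t(pairSe)
  pk <- df$value[df$kind == "pk"]
  pkSe <- df$se[df$kind == "pk"]
  new("MomentSet", mean = m, pair = pair, pk = pk / sum(pk),
      se = list(mean = mSe, pair = pairSe, pk = pkSe), nBins = nb)
}

#' Write / read a K-pairwise model file (bit-exact round trip)
#'
#' Text format with a header (\code{N}, fitted mask as 0/1) and sections
#' \code{[h]} (i value), \code{[J]} (i j value triplets, upper triangle)
#' and \code{[V]} (K value pairs).  Values are written with full
#' \code{\%.17g} precision so that read(write(m)) reproduces the doubles
#' bit for bit.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param path file path.
#' @export
writeKPairwiseModel <- function(model, path) {
  n <- length(model@h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#N=", n),
               paste0("#fitted=", paste(as.integer(model@fittedMask),
                                        collapse = ""))), con)
  writeLines("[h]", con)
  writeLines(sprintf("%d\t%.17g", seq_len(n), model@h), con)
  writeLines("[J]", con)
  pi <- pairIndices(n)
  writeLines(sprintf("%d\t%d\t%.17g", pi[, 1], pi[, 2], model@J[pi]), con)
  writeLines("[V]", con)
  writeLines(sprintf("%d\t%.17g", 0:n, model@V), con)
  invisible(path)
}

#' @rdname writeKPairwiseModel
#' @export
readKPairwiseModel <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^#N=", "", grep("^#N=", lines, value = TRUE)[1]))
  maskStr <- sub("^#fitted=", "", grep("^#fitted=", lines, value = TRUE)[1])
  mask <- as.integer(strsplit(maskStr, "")[[1]]) == 1L
  sec <- function(name) {
    start <- which(lines == paste0("[", name, "]")) + 1
    endCands <- c(grep("^\\[", lines), length(lines) + 1)
    end <- min(endCands[endCands >= start]) - 1
    lines[start:end]
  }
  hrows <- do.call(rbind, strsplit(sec("h"), "\t"))
  h <- numeric(n); h[as.integer(hrows[, 1])] <- as.numeric(hrows[, 2])
  J <- matrix(0, n, n)
  jrows <- do.call(rbind, strsplit(sec("J"), "\t"))
  J[cbind(as.integer(jrows[, 1]), as.integer(jrows[, 2]))] <-
    as.numeric(jrows[, 3])
  J <- J + t(J)
  vrows <- do.call(rbind, strsplit(sec("V"), "\t"))
  V <- numeric(n + 1)
  V[as.integer(vrows[, 1]) + 1L] <- as.numeric(vrows[, 2])
  new("KPairwiseModel", h = h, J = J, V = V, fittedMask = mask)
}

#' Export a thermodynamic response curve
#'
#' Tab-separated columns T, cv, cv_se, chi, chi_se, init_mode.
#'
#' @param curve a \linkS4class{ThermoCurve}.
#' @param path file path.
#' @export
writeThermoCurve <- function(curve, path) {
  df <- curveTable(curve)
  names(df) <- c("T", "cv", "cv_se", "chi", "chi_se", "init_mode")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file into dynamics parameters
#'
#' Lines of the form \code{key = value} (or \code{key=value}); keys mirror
#' the \linkS4class{DynamicsParams} slot names; \code{#} comments and
#' blank lines are ignored.
#'
#' @param path file path.
#' @return a \linkS4class{DynamicsParams}.
#' @export
readDynamicsConfig <- function(path) {
  kv <- readKeyValue(path)
  args <- list()
  for (slotName in c("vThreshold", "deltaU", "deltaURec", "deltaV", "beta",
                     "gMin", "pretrainAvalanches"))
    if (slotName %in% names(kv)) args[[slotName]] <- as.numeric(kv[[slotName]])
  do.call(dynamicsParams, args)
}

readKeyValue <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(parts, `[`, 2), vapply(parts, `[`, "", 1))
}
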