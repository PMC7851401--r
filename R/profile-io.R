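# On-disk profile format (".jdp"): little-endian fixed-width integers.
#
#   header : magic "JDPF", version int32, sample id, read length,
#            sequence dictionary, per-read-group histograms
#   blocks : one per contig with records, columnar --
#            zig-zag delta-encoded fwdStart int32[n], insertSize int32[n],
#            readGroup int32[n]
#   index  : per block, one entry per 2^16 bp bucket: (bucketStart,
#            first record index >= bucketStart, decoding anchor position)
#   trailer: byte offset of the index section (double) + magic "JDPX"

JDP_MAGIC <- charToRaw("JDPF")
JDP_END_MAGIC <- charToRaw("JDPX")
JDP_VERSION <- 1L
JDP_BUCKET <- 65536L

zigzag <- function(x) ifelse(x >= 0L, 2L * x, -2L * x - 1L)
unzigzag <- function(z) ifelse(z %% 2L == 0L, z %/% 2L, -((z + 1L) %/% 2L))

writeStr <- function(con, s) {
  r <- charToRaw(enc2utf8(s))
  writeBin(length(r), con, size = 4L, endian = "little")
  writeBin(r, con)
}

readInt <- function(con, n = 1L) {
  v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(v) != n) stop("truncated profile file")
  v
}

readDbl <- function(con, n = 1L) {
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(v) != n) stop("truncated profile file")
  v
}

readStr <- function(con) {
  n <- readInt(con)
  r <- readBin(con, "raw", n = n)
  if (length(r) != n) stop("truncated profile file")
  rawToChar(r)
}

writeHeader <- function(con, profile) {
  writeBin(JDP_MAGIC, con)
  writeBin(JDP_VERSION, con, size = 4L, endian = "little")
  writeStr(con, profile@sampleId)
  writeBin(profile@readLen, con, size = 4L, endian = "little")
  sq <- profile@seqlengths
  writeBin(length(sq), con, size = 4L, endian = "little")
  for (i in seq_along(sq)) {
    writeStr(con, names(sq)[i])
    writeBin(as.integer(sq[i]), con, size = 4L, endian = "little")
  }
  hs <- profile@histograms
  writeBin(length(hs), con, size = 4L, endian = "little")
  for (h in hs) {
    writeBin(h@readGroup, con, size = 4L, endian = "little")
    writeBin(h@offset, con, size = 4L, endian = "little")
    writeBin(length(h@counts), con, size = 4L, endian = "little")
    writeBin(c(h@mean, h@sd, h@total), con, size = 8L, endian = "little")
    writeBin(as.integer(h@counts), con, size = 4L, endian = "little")
  }
}

readHeader <- function(con) {
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, JDP_MAGIC))
    stop("not a profile file (bad magic bytes)")
  version <- readInt(con)
  if (version != JDP_VERSION)
    stop(sprintf("profile version mismatch: expected %d, found %d",
                 JDP_VERSION, version))
  sampleId <- readStr(con)
  readLen <- readInt(con)
  nc <- readInt(con)
  nms <- character(nc)
  lens <- integer(nc)
  for (i in seq_len(nc)) {
    nms[i] <- readStr(con)
    lens[i] <- readInt(con)
  }
  nh <- readInt(con)
  hists <- vector("list", nh)
  for (i in seq_len(nh)) {
    rg <- readInt(con)
    off <- readInt(con)
    ncounts <- readInt(con)
    mo <- readDbl(con, 3L)
    counts <- readInt(con, ncounts)
    hists[[i]] <- new("InsertSizeHistogram", counts = as.numeric(counts),
                      offset = off, mean = mo[1], sd = mo[2], total = mo[3],
                      readGroup = rg)
  }
  names(hists) <- vapply(hists, function(h) as.character(h@readGroup), "")
  list(sampleId = sampleId, readLen = readLen,
       seqlengths = setNames(lens, nms), histograms = hists)
}

#' Write a read-pair profile to disk
#'
#' Serialises a \code{\link{ReadPairProfile}} into the indexed binary
#' \code{.jdp} format. Positions are zig-zag delta-encoded per contig and an
#' index entry every 2^16 bp permits seeking to genomic positions without
#' decoding the whole file (\code{\link{profileSeek}}).
#'
#' @param profile a \code{ReadPairProfile}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readProfile}}, \code{\link{profileSeek}}
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ReadPairProfile"))
  validObject(profile)
  con <- file(path, "wb")
  on.exit(close(con))
  writeHeader(con, profile)
  r <- profile@records
  contigs <- sort(unique(r$contig))
  blocks <- vector("list", length(contigs))
  for (bi in seq_along(contigs)) {
    rb <- r[r$contig == contigs[bi], , drop = FALSE]
    off <- seek(con)                       # current byte offset
    pos <- rb$fwdStart
    deltas <- zigzag(as.integer(diff(c(0L, pos))))
    writeBin(deltas, con, size = 4L, endian = "little")
    writeBin(as.integer(rb$insertSize), con, size = 4L, endian = "little")
    writeBin(as.integer(rb$readGroup), con, size = 4L, endian = "little")
    nIdx <- max(pos) %/% JDP_BUCKET + 1L
    bucketStarts <- (seq_len(nIdx) - 1L) * JDP_BUCKET
    recIdx <- findInterval(bucketStarts - 0.5, pos)  # records strictly before bucket
    anchor <- ifelse(recIdx > 0L, pos[pmax(recIdx, 1L)], 0L)
    blocks[[bi]] <- list(contig = contigs[bi], offset = off,
                         n = nrow(rb), bucketStarts = bucketStarts,
                         recIdx = as.integer(recIdx), anchor = as.integer(anchor))
  }
  idxOff <- seek(con)
  writeBin(length(blocks), con, size = 4L, endian = "little")
  for (b in blocks) {
    writeBin(c(b$contig, 0L), con, size = 4L, endian = "little")  # reserved
    writeBin(as.double(b$offset), con, size = 8L, endian = "little")
    writeBin(c(b$n, length(b$bucketStarts)), con, size = 4L, endian = "little")
    writeBin(as.integer(rbind(b$bucketStarts, b$recIdx, b$anchor)), con,
             size = 4L, endian = "little")
  }
  writeBin(as.double(idxOff), con, size = 8L, endian = "little")
  writeBin(JDP_END_MAGIC, con)
  invisible(path)
}

readIndex <- function(con) {
  seek(con, -12L, origin = "end")
  idxOff <- readDbl(con)
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, JDP_END_MAGIC))
    stop("truncated or corrupt profile file (missing end magic)")
  seek(con, idxOff)
  nb <- readInt(con)
  blocks <- vector("list", nb)
  for (i in seq_len(nb)) {
    ci <- readInt(con, 2L)[1]
    off <- readDbl(con)
    nn <- readInt(con, 2L)
    ent <- matrix(readInt(con, 3L * nn[2]), nrow = 3L)
    blocks[[i]] <- list(contig = ci, offset = off, n = nn[1],
                        bucketStarts = ent[1, ], recIdx = ent[2, ],
                        anchor = ent[3, ])
  }
  blocks
}

decodeBlock <- function(con, block, fromRec = 0L, anchor = 0L) {
  n <- block$n - fromRec
  if (n <= 0L)
    return(data.frame(contig = integer(), fwdStart = integer(),
                      insertSize = integer(), readGroup = integer()))
  seek(con, block$offset + 4L * fromRec)
  deltas <- unzigzag(readInt(con, n))
  pos <- as.integer(cumsum(c(anchor + deltas[1], deltas[-1])))
  seek(con, block$offset + 4L * block$n + 4L * fromRec)
  ins <- readInt(con, n)
  seek(con, block$offset + 8L * block$n + 4L * fromRec)
  rg <- readInt(con, n)
  data.frame(contig = rep(block$contig, n), fwdStart = pos,
             insertSize = ins, readGroup = rg)
}

#' Read a full profile from disk
#'
#' @param path path to a \code{.jdp} file written by
#'   \code{\link{writeProfile}}.
#' @return the reconstructed \code{\link{ReadPairProfile}}; the round trip
#'   is lossless.
#' @export
readProfile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readHeader(con)
  blocks <- readIndex(con)
  recs <- lapply(blocks, function(b) decodeBlock(con, b))
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(contig = integer(), fwdStart = integer(),
               insertSize = integer(), readGroup = integer())
  rownames(records) <- NULL
  new("ReadPairProfile", sampleId = hdr$sampleId,
      seqlengths = hdr$seqlengths, histograms = hdr$histograms,
      records = records, readLen = hdr$readLen)
}

#' Seek into a profile file
#'
#' Uses the positional index to return every record on \code{contig} with
#' forward start >= \code{pos} without decoding the rest of the file.
#'
#' @param path path to a \code{.jdp} file.
#' @param contig contig name.
#' @param pos 0-based genomic position.
#' @return data.frame of records (columns as in
#'   \code{\link{ReadPairProfile}}).
#' @export
profileSeek <- function(path, contig, pos) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readHeader(con)
  ci <- match(contig, names(hdr$seqlengths))
  if (is.na(ci)) stop("contig not in profile sequence dictionary: ", contig)
  blocks <- readIndex(con)
  bi <- which(vapply(blocks, function(b) b$contig, 1L) == ci)
  empty <- data.frame(contig = integer(), fwdStart = integer(),
                      insertSize = integer(), readGroup = integer())
  if (!length(bi)) return(empty)
  b <- blocks[[bi]]
  k <- findInterval(pos, b$bucketStarts)   # last bucket starting <= pos
  if (k < 1L) k <- 1L
  recs <- decodeBlock(con, b, fromRec = b$recIdx[k], anchor = b$anchor[k])
  out <- recs[recs$fwdStart >= pos, , drop = FALSE]
  rownames(out) <- NULL
  out
}
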