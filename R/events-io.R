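## Event-table input/output.
##
## The canonical on-disk format is a plain CSV with a mandatory header row
## (channel names) and a JSON sidecar (<path>.json) carrying channel roles,
## units and the provenance log.  A minimal FCS 3.1 list-mode reader/writer
## (float32 data, little-endian) is provided for interoperability with
## cytometry acquisition software; the analysis segment is ignored.

#' Read an event table
#'
#' @param path file path.
#' @param format "csv" or "fcs".
#' @param roles named character vector mapping channel names to roles; for
#'   CSV it overrides (or supplements) the sidecar, for FCS it maps the
#'   $PnN parameter names.  Channels not named default to "epitope"
#'   (\code{truth_}-prefixed columns to "truth").
#' @param require_dna error unless a \code{dna_integral} channel is present
#'   after role assignment (default TRUE: the pipeline is meaningless
#'   without DNA content).
#' @return a \linkS4class{CytoFrame}.
#' @export
readEvents <- function(path, format = c("csv", "fcs"), roles = NULL,
                       require_dna = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  cf <- switch(format,
    csv = .read_events_csv(path, roles),
    fcs = .read_events_fcs(path, roles)
  )
  if (require_dna && !length(channelByRole(cf, "dna_integral")))
    stop("no channel with role dna_integral; supply one via `roles`")
  cf
}

#' Write an event table
#'
#' CSV output writes a JSON sidecar (<path>.json) with channel metadata and
#' provenance.  FCS output writes an FCS 3.1 list-mode file with float32
#' data (truth columns included as ordinary parameters).
#'
#' @param table a \linkS4class{CytoFrame}.
#' @param path output file path.
#' @param format "csv" or "fcs".
#' @return the path, invisibly.
#' @export
writeEvents <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(is(table, "CytoFrame"))
  switch(format,
    csv = .write_events_csv(table, path),
    fcs = .write_events_fcs(table, path)
  )
  invisible(path)
}

.apply_roles <- function(m, roles) {
  nm <- colnames(m)
  r <- ifelse(startsWith(nm, "truth_"), "truth", "epitope")
  names(r) <- nm
  ## conventional channel names get their conventional roles
  if ("dna" %in% nm && !"dna" %in% names(roles)) r["dna"] <- "dna_integral"
  if ("dna_h" %in% nm && !"dna_h" %in% names(roles)) r["dna_h"] <- "dna_height"
  if (length(roles)) {
    missing <- setdiff(names(roles), nm)
    if (length(missing))
      stop("role map names channel(s) absent from the file: ",
           paste(missing, collapse = ", "))
    r[names(roles)] <- roles
  }
  r
}

.read_events_csv <- function(path, roles) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  side <- paste0(path, ".json")
  prov <- list()
  side_roles <- character()
  units <- character()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$channels)) {
      side_roles <- stats::setNames(meta$channels$role, meta$channels$name)
      units <- stats::setNames(meta$channels$units, meta$channels$name)
      side_roles <- side_roles[names(side_roles) %in% colnames(m)]
      units <- units[names(units) %in% colnames(m)]
    }
    if (!is.null(meta$provenance)) prov <- as.list(meta$provenance)
  }
  r <- .apply_roles(m, roles)
  r[names(side_roles)] <- side_roles
  if (length(roles)) r[names(roles)] <- roles
  CytoFrame(m, roles = r, units = units, provenance = prov)
}

.write_events_csv <- function(table, path) {
  utils::write.csv(as.data.frame(intensities(table)), path,
                   row.names = FALSE)
  cd <- channelData(table)
  meta <- list(
    channels = data.frame(name = as.character(cd$name),
                          role = as.character(cd$role),
                          units = as.character(cd$units)),
    provenance = unlist(provenance(table), use.names = FALSE)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

## ---- minimal FCS 3.1 (list mode, $DATATYPE/F, little-endian) ----

.read_events_fcs <- function(path, roles) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (!startsWith(header, "FCS3"))
    stop("not an FCS 3.x file: ", path)
  off <- function(i) {
    as.integer(trimws(substr(header, 10 + (i - 1) * 8 + 1, 10 + i * 8)))
  }
  t0 <- off(1); t1 <- off(2); d0 <- off(3); d1 <- off(4)
  seek(con, t0)
  text <- rawToChar(readBin(con, "raw", t1 - t0 + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(parts[seq(1, length(parts), 2)]))
  np <- as.integer(kw[["$PAR"]])
  ne <- as.integer(kw[["$TOT"]])
  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("only $DATATYPE/F (float) FCS data is supported")
  if (d0 == 0 && "$BEGINDATA" %in% names(kw)) {
    d0 <- as.integer(kw[["$BEGINDATA"]]); d1 <- as.integer(kw[["$ENDDATA"]])
  }
  little <- !identical(kw[["$BYTEORD"]], "4,3,2,1")
  nms <- vapply(seq_len(np), function(i) kw[[sprintf("$P%dN", i)]],
                character(1))
  seek(con, d0)
  vals <- readBin(con, "double", n = np * ne, size = 4,
                  endian = if (little) "little" else "big")
  m <- matrix(vals, ncol = np, byrow = TRUE, dimnames = list(NULL, nms))
  CytoFrame(m, roles = .apply_roles(m, roles),
            provenance = list(sprintf("readEvents: fcs %s", basename(path))))
}

.write_events_fcs <- function(table, path) {
  m <- intensities(table)
  np <- ncol(m); ne <- nrow(m)
  delim <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", np, "$TOT", ne, "$NEXTDATA", "0")
  for (i in seq_len(np)) {
    rng <- max(1, ceiling(max(m[, i], 0, na.rm = TRUE)))
    kv <- c(kv, sprintf("$P%dN", i), colnames(m)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(rng, scientific = FALSE))
  }
  build_text <- function(begindata, enddata) {
    paste0(delim, paste(c(kv, "$BEGINDATA", begindata, "$ENDDATA", enddata),
                        collapse = delim), delim)
  }
  ## iterate once: text length depends on the data offsets it declares
  t0 <- 58L
  txt <- build_text(0, 0)
  for (i in 1:3) {
    d0 <- t0 + nchar(txt)
    d1 <- d0 + 4L * np * ne - 1L
    txt2 <- build_text(d0, d1)
    if (nchar(txt2) == nchar(txt)) { txt <- txt2; break }
    txt <- txt2
  }
  d0 <- t0 + nchar(txt); d1 <- d0 + 4L * np * ne - 1L
  fmt8 <- function(x) formatC(x, width = 8, flag = " ")
  ## 58-byte header: version, text/data/analysis begin-end offsets
  header <- paste0("FCS3.1    ", fmt8(t0), fmt8(t0 + nchar(txt) - 1L),
                   fmt8(if (d1 <= 99999999) d0 else 0),
                   fmt8(if (d1 <= 99999999) d1 else 0),
                   fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
}
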