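#' Construct a piecewise-constant ligand protocol
#'
#' @param start segment start times (s); first must be 0.
#' @param fkbp12,fkbp12_6 concentrations (uM) per segment, recycled.
#' @param description label.
#' @return A \linkS4class{ConcentrationProtocol}.
#' @examples
#' # control, then 200 nM FKBP12.6 at t = 120 s
#' ConcentrationProtocol(c(0, 120), fkbp12 = 0, fkbp12_6 = c(0, 0.2))
#' @export
ConcentrationProtocol <- function(start, fkbp12 = 0, fkbp12_6 = 0,
    description = "") {
  n <- length(start)
  seg <- data.frame(start = as.numeric(start),
    fkbp12 = rep_len(as.numeric(fkbp12), n),
    fkbp12_6 = rep_len(as.numeric(fkbp12_6), n))
  new("ConcentrationProtocol", segments = seg, description = description)
}

#' @rdname ConcentrationProtocol
#' @export
constantProtocol <- function(fkbp12 = 0, fkbp12_6 = 0, description = "") {
  ConcentrationProtocol(0, fkbp12, fkbp12_6, description)
}

#' Read / write a ligand protocol (YAML or JSON)
#'
#' File format: a list of segments, each with keys \code{t} (s),
#' \code{fkbp12_uM} and \code{fkbp12_6_uM}.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return A \linkS4class{ConcentrationProtocol}.
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  raw <- .read_config(path)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  if (!length(raw)) stop("empty protocol file: ", path)
  seg <- lapply(raw, function(s) {
    bad <- setdiff(names(s), c("t", "fkbp12_uM", "fkbp12_6_uM"))
    if (length(bad))
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "))
    data.frame(start = as.numeric(s$t),
      fkbp12 = as.numeric(s$fkbp12_uM %||% 0),
      fkbp12_6 = as.numeric(s$fkbp12_6_uM %||% 0))
  })
  seg <- do.call(rbind, seg)
  new("ConcentrationProtocol", segments = seg,
    description = basename(path))
}

#' @rdname readProtocol
#' @param protocol a \linkS4class{ConcentrationProtocol} to write.
#' @export
writeProtocol <- function(protocol, path) {
  seg <- protocol@segments
  out <- lapply(seq_len(nrow(seg)), function(i)
    list(t = seg$start[i], fkbp12_uM = seg$fkbp12[i],
      fkbp12_6_uM = seg$fkbp12_6[i]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concentrations in force at a given time
#' @param protocol a \linkS4class{ConcentrationProtocol}.
#' @param time time (s).
#' @return A \linkS4class{LigandConcentrations}.
#' @export
concentrationsAt <- function(protocol, time) {
  seg <- protocol@segments
  i <- findInterval(time, seg$start)
  if (i < 1L) i <- 1L
  LigandConcentrations(seg$fkbp12[i], seg$fkbp12_6[i])
}

setMethod("show", "ConcentrationProtocol", function(object) {
  cat("ConcentrationProtocol")
  if (nzchar(object@description)) cat(" [", object@description, "]", sep = "")
  cat(":", nrow(object@segments), "segment(s)\n")
  print(object@segments, row.names = FALSE)
})
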