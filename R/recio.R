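#' Write a recording set to the native HDF5 container
#'
#' Schema: one group per recording under \code{/recordings/<id>} holding the
#' \code{traces} dataset (n_sweeps x n_samples, float64) and the attributes
#' \code{holding}, \code{steps}, \code{onset}, \code{offset}, \code{duration},
#' \code{rate}, \code{capacitance}, \code{label}, \code{meta} (JSON) and,
#' when a split assignment exists, \code{split}. Round-trips bit-exactly with
#' \code{\link{read_container}}.
#'
#' @param set A \code{\link{recording_set}}.
#' @param path Output file path (overwritten if present).
#' @return Invisibly, \code{path}.
#' @export
write_container <- function(set, path) {
  if (!inherits(set, "recording_set")) stop("set must be a recording_set")
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop(sprintf("path not writable: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "recordings")
  fid <- rhdf5::H5Fopen(path)
  root <- rhdf5::H5Gopen(fid, "recordings")
  rhdf5::h5writeAttribute(1L, root, "schema_version")
  rhdf5::H5Gclose(root)
  for (i in seq_along(set$recordings)) {
    r <- set$recordings[[i]]
    gname <- sprintf("recordings/rec_%05d", i)
    rhdf5::h5createGroup(fid, gname)
    rhdf5::h5write(r$traces, fid, paste0(gname, "/traces"))
    gid <- rhdf5::H5Gopen(fid, gname)
    p <- r$protocol
    rhdf5::h5writeAttribute(p$holding, gid, "holding")
    rhdf5::h5writeAttribute(p$steps, gid, "steps")
    rhdf5::h5writeAttribute(p$onset, gid, "onset")
    rhdf5::h5writeAttribute(p$offset, gid, "offset")
    rhdf5::h5writeAttribute(p$duration, gid, "duration")
    rhdf5::h5writeAttribute(p$rate, gid, "rate")
    rhdf5::h5writeAttribute(r$capacitance, gid, "capacitance")
    rhdf5::h5writeAttribute(r$label, gid, "label")
    rhdf5::h5writeAttribute(
      as.character(jsonlite::toJSON(r$meta, auto_unbox = TRUE)), gid, "meta")
    if (!is.null(set$split))
      rhdf5::h5writeAttribute(set$split[i], gid, "split")
    rhdf5::H5Gclose(gid)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a recording set from the native HDF5 container
#'
#' @param path File written by \code{\link{write_container}} (or conforming
#'   to its documented schema).
#' @return A \code{\link{recording_set}}.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  groups <- sort(ls$name[ls$group == "/recordings" & ls$otype == "H5I_GROUP"])
  required <- c("holding", "steps", "onset", "offset", "duration", "rate",
                "capacitance", "label")
  recs <- vector("list", length(groups))
  split <- character(length(groups))
  has_split <- FALSE
  for (i in seq_along(groups)) {
    gname <- paste0("recordings/", groups[i])
    at <- rhdf5::h5readAttributes(path, gname)
    missing <- setdiff(required, names(at))
    if (length(missing))
      stop(sprintf("malformed container schema: group '%s' is missing attribute '%s'",
                   gname, missing[1]))
    traces <- rhdf5::h5read(path, paste0(gname, "/traces"))
    proto <- voltage_protocol(at$holding, as.numeric(at$steps), at$onset,
                              at$offset, at$duration, at$rate)
    meta <- if (!is.null(at$meta)) jsonlite::fromJSON(at$meta) else list()
    recs[[i]] <- recording(traces, proto, at$capacitance, at$label, meta)
    if (!is.null(at$split)) { has_split <- TRUE; split[i] <- at$split }
  }
  recording_set(recs, split = if (has_split) split else NULL)
}

#' Export one recording as CSV
#'
#' One \code{time_ms} column plus one current column per sweep; the header
#' names each sweep by its step potential (e.g. \code{step_-40mV}). Values
#' are written at full double precision.
#'
#' @param rec A \code{\link{recording}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
export_csv <- function(rec, path) {
  df <- data.frame(time_ms = time_axis(rec$protocol), t(rec$traces),
                   check.names = FALSE)
  names(df)[-1] <- sprintf("step_%gmV", rec$protocol$steps)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a recording from CSV
#'
#' @param path CSV written by \code{\link{export_csv}} (time column followed
#'   by one column per sweep).
#' @param protocol The \code{\link{voltage_protocol}} the file was acquired
#'   under; the column count must match its step count.
#' @param capacitance Membrane capacitance, pF.
#' @param label Optional label (default \code{"unknown"}).
#' @return A \code{\link{recording}}.
#' @export
import_csv <- function(path, protocol, capacitance, label = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  n_cur <- ncol(df) - 1L
  if (n_cur != length(protocol$steps))
    stop(sprintf("CSV has %d current columns but the protocol defines %d steps",
                 n_cur, length(protocol$steps)))
  if (nrow(df) != n_samples(protocol))
    stop(sprintf("CSV has %d rows but the protocol defines %d samples",
                 nrow(df), n_samples(protocol)))
  recording(t(as.matrix(df[, -1L, drop = FALSE])), protocol, capacitance,
            label = label)
}
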