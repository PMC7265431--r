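#' Write a run to a toffee HDF5 file
#'
#' Persists the run with the fixed layout: root attributes
#' `CREATED_BY_LIBRARY_VERSION`, `FILE_FORMAT_MAJOR_VERSION`,
#' `FILE_FORMAT_MINOR_VERSION`, `IMSType`, `metadataXML`; one group per
#' window (`ms1`, `ms2-001`, ...) carrying attributes `IMSAlpha`, `IMSBeta`
#' (window medians), `IMSGamma`, `firstScanRetentionTimeOffset`,
#' `scanCycleTime`, `precursorLower`, `precursorCenter`, `precursorUpper`
#' and datasets `IMSAlphaPerScan`, `IMSBetaPerScan` (double) plus the CSR
#' triplet store `retentionTimeIdx`, `imsCoord`, `intensity` (unsigned
#' 32-bit, zlib-compressed).
#'
#' @param run a [toffee_run].
#' @param path output file path (overwritten if it exists).
#' @param compression_level zlib level 0-9 (default 6).
#' @return `path`, invisibly.
#' @export
write_toffee <- function(run, path, compression_level = 6L) {
  validate_run(run)
  u32_max <- 4294967295
  for (w in run$windows) {
    for (field in c("imsCoord", "intensity", "retentionTimeIdx")) {
      v <- w$csr[[field]]
      if (length(v) && max(v) > u32_max) {
        bad <- which.max(v)
        scan <- findInterval(bad - 1, c(0, w$csr$retentionTimeIdx))
        stop(sprintf(
          "window '%s': %s value %.0f exceeds unsigned 32-bit range (near scan %d)",
          w$name, field, max(v), scan - 1L))
      }
    }
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  fid <- rhdf5::H5Fopen(path)
  h5_attr_str <- function(loc, name, value) {
    rhdf5::h5writeAttribute(value, loc, name, variableLengthString = TRUE,
                            asScalar = TRUE)
  }
  h5_attr_str(fid, "CREATED_BY_LIBRARY_VERSION", run$createdByVersion)
  rhdf5::h5writeAttribute(run$formatMajor, fid, "FILE_FORMAT_MAJOR_VERSION")
  rhdf5::h5writeAttribute(run$formatMinor, fid, "FILE_FORMAT_MINOR_VERSION")
  h5_attr_str(fid, "IMSType", run$imsType)
  h5_attr_str(fid, "metadataXML", run$metadataXML)
  rhdf5::H5Fclose(fid)

  for (w in run$windows) {
    g <- w$name
    rhdf5::h5createGroup(path, g)
    write_u32 <- function(name, values) {
      ds <- paste0(g, "/", name)
      n <- length(values)
      rhdf5::h5createDataset(path, ds, dims = n, H5type = "H5T_STD_U32LE",
                             level = as.integer(compression_level),
                             chunk = max(1L, min(n, 16384L)))
      if (n) rhdf5::h5write(values, path, ds)
    }
    write_dbl <- function(name, values) {
      ds <- paste0(g, "/", name)
      n <- length(values)
      rhdf5::h5createDataset(path, ds, dims = n, storage.mode = "double",
                             level = as.integer(compression_level),
                             chunk = max(1L, min(n, 16384L)))
      if (n) rhdf5::h5write(values, path, ds)
    }
    write_dbl("IMSAlphaPerScan", w$alphaPerScan)
    write_dbl("IMSBetaPerScan", w$betaPerScan)
    write_u32("retentionTimeIdx", w$csr$retentionTimeIdx)
    write_u32("imsCoord", w$csr$imsCoord)
    write_u32("intensity", w$csr$intensity)

    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(w$medianAlpha, gid, "IMSAlpha")
    rhdf5::h5writeAttribute(w$medianBeta, gid, "IMSBeta")
    rhdf5::h5writeAttribute(w$gamma, gid, "IMSGamma")
    rhdf5::h5writeAttribute(w$firstScanRetentionTimeOffset, gid,
                            "firstScanRetentionTimeOffset")
    rhdf5::h5writeAttribute(w$scanCycleTime, gid, "scanCycleTime")
    rhdf5::h5writeAttribute(w$precursorLower, gid, "precursorLower")
    rhdf5::h5writeAttribute(w$precursorCenter, gid, "precursorCenter")
    rhdf5::h5writeAttribute(w$precursorUpper, gid, "precursorUpper")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read a toffee HDF5 file into a run model
#'
#' Loads and fully validates the file; structural invariant violations
#' (missing `ms1` group, decreasing `retentionTimeIdx`, mismatched vector
#' lengths, ...) raise a corrupt-file error naming the failed invariant,
#' and an unsupported major format version raises a version error.
#'
#' @param path toffee file path.
#' @return A validated [toffee_run].
#' @export
read_toffee <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  root <- rhdf5::h5readAttributes(path, "/")
  need <- c("CREATED_BY_LIBRARY_VERSION", "FILE_FORMAT_MAJOR_VERSION",
            "FILE_FORMAT_MINOR_VERSION", "IMSType", "metadataXML")
  miss <- setdiff(need, names(root))
  if (length(miss)) {
    stop(sprintf("corrupt toffee file: missing root attribute(s) %s",
                 paste(miss, collapse = ", ")))
  }
  major <- as.integer(root$FILE_FORMAT_MAJOR_VERSION)
  if (major > 1L) {
    stop(sprintf("unsupported toffee file format major version %d", major))
  }
  contents <- rhdf5::h5ls(path, recursive = FALSE)
  groups <- contents$name[contents$otype == "H5I_GROUP"]
  if (!("ms1" %in% groups)) {
    stop("corrupt toffee file: missing group 'ms1'")
  }
  windows <- lapply(sort(groups), function(g) {
    at <- rhdf5::h5readAttributes(path, g)
    rd <- function(name) {
      as.numeric(rhdf5::h5read(path, paste0(g, "/", name),
                               bit64conversion = "double"))
    }
    csr <- structure(list(retentionTimeIdx = rd("retentionTimeIdx"),
                          imsCoord = rd("imsCoord"),
                          intensity = rd("intensity")),
                     class = "csr_map")
    w <- structure(list(
      name = g,
      precursorLower = as.numeric(at$precursorLower),
      precursorCenter = as.numeric(at$precursorCenter),
      precursorUpper = as.numeric(at$precursorUpper),
      firstScanRetentionTimeOffset = as.numeric(at$firstScanRetentionTimeOffset),
      scanCycleTime = as.numeric(at$scanCycleTime),
      medianAlpha = as.numeric(at$IMSAlpha),
      medianBeta = as.numeric(at$IMSBeta),
      gamma = as.integer(at$IMSGamma),
      alphaPerScan = rd("IMSAlphaPerScan"),
      betaPerScan = rd("IMSBetaPerScan"),
      csr = csr), class = "toffee_window")
    tryCatch(validate_window(w),
             error = function(e) stop(sprintf("corrupt toffee file: %s",
                                              conditionMessage(e))))
    w
  })
  names(windows) <- vapply(windows, `[[`, "", "name")
  run <- structure(list(
    createdByVersion = as.character(root$CREATED_BY_LIBRARY_VERSION),
    formatMajor = major,
    formatMinor = as.integer(root$FILE_FORMAT_MINOR_VERSION),
    imsType = as.character(root$IMSType),
    metadataXML = as.character(root$metadataXML),
    windows = windows), class = "toffee_run")
  tryCatch(validate_run(run),
           error = function(e) stop(sprintf("corrupt toffee file: %s",
                                            conditionMessage(e))))
  run
}

#' Inspect the on-disk layout of a toffee file
#'
#' Returns the attribute and dataset names (with dataset types) actually
#' present in the file, for checking format fidelity against the canonical
#' layout manifest shipped in `inst/extdata/toffee-manifest.txt`.
#'
#' @param path toffee file path.
#' @return data.frame with columns `where`, `kind`, `name`, `dtype`.
#' @export
toffee_layout <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  out <- list()
  add <- function(where, kind, name, dtype = "") {
    out[[length(out) + 1L]] <<- data.frame(where = where, kind = kind,
                                           name = name, dtype = dtype)
  }
  for (a in names(rhdf5::h5readAttributes(path, "/"))) add("/", "attr", a)
  contents <- rhdf5::h5ls(path, all = TRUE)
  groups <- sort(contents$name[contents$group == "/" &
                                 contents$otype == "H5I_GROUP"])
  for (g in groups) {
    for (a in names(rhdf5::h5readAttributes(path, g))) add(g, "attr", a)
    ds <- contents[contents$group == paste0("/", g) &
                     contents$otype == "H5I_DATASET", , drop = FALSE]
    ds <- ds[order(ds$name), , drop = FALSE]
    for (i in seq_len(nrow(ds))) add(g, "dataset", ds$name[i], ds$dtype[i])
  }
  do.call(rbind, out)
}
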