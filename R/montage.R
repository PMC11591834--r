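# The 24-channel montage and its five-region partition.

#' Default 24-channel montage
#'
#' Channel-to-region map used throughout the package: 9 frontal, 2 temporal,
#' 5 central, 5 parietal and 3 occipital electrodes from the 10-10 system.
#'
#' @return data.frame with columns `label` and `region`.
#' @export
#' @examples
#' table(default_montage()$region)
default_montage <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "AF3", "AF4", "F7", "Fz", "F8", "FC5", "FC6",
              "FT7", "FT8",
              "C3", "Cz", "C4", "CP3", "CP4",
              "P3", "Pz", "P4", "PO3", "PO4",
              "O1", "Oz", "O2"),
    region = c(rep("frontal", 9),
               rep("temporal", 2),
               rep("central", 5),
               rep("parietal", 5),
               rep("occipital", 3)),
    # approximate 2D scalp projection (unit head disc), used by the
    # synthetic generator's distance-dependent coupling
    x = c(-0.31, 0.31, -0.35, 0.35, -0.81, 0, 0.81, -0.59, 0.59,
          -0.95, 0.95,
          -0.40, 0, 0.40, -0.36, 0.36,
          -0.36, 0, 0.36, -0.35, 0.35,
          -0.31, 0, 0.31),
    y = c(0.95, 0.95, 0.80, 0.80, 0.59, 0.60, 0.59, 0.31, 0.31,
          0.31, 0.31,
          0, 0, 0, -0.30, -0.30,
          -0.59, -0.60, -0.59, -0.80, -0.80,
          -0.95, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

plv_regions <- c("frontal", "temporal", "central", "parietal", "occipital")

#' Read a montage from CSV or JSON
#'
#' CSV needs columns `label, region` (optional `x, y, z`); JSON either that
#' record layout or a `{label: region}` map.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `region` (plus any coordinates).
#' @export
read_montage <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(obj)) {
      m <- obj
    } else {
      m <- data.frame(label = names(obj), region = unlist(obj),
                      stringsAsFactors = FALSE)
    }
  } else {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_montage(m)
  rownames(m) <- NULL
  m
}

#' @rdname read_montage
#' @param montage data.frame as returned by [default_montage()].
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  utils::write.csv(montage, path, row.names = FALSE)
  invisible(path)
}

validate_montage <- function(m) {
  if (!all(c("label", "region") %in% names(m))) {
    stop("montage must have columns 'label' and 'region'")
  }
  if (anyDuplicated(m$label)) stop("montage labels must be unique")
  bad <- setdiff(unique(m$region), plv_regions)
  if (length(bad)) {
    stop("unknown montage region(s): ", paste(bad, collapse = ", "))
  }
  invisible(m)
}

#' Map channels to regions
#'
#' @param labels character vector of channel labels.
#' @param montage montage data.frame; defaults to [default_montage()].
#' @return character vector of regions aligned with `labels`.
#' @export
channel_regions <- function(labels, montage = default_montage()) {
  idx <- match(labels, montage$label)
  if (anyNA(idx)) {
    stop("channel(s) missing from montage: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  montage$region[idx]
}
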