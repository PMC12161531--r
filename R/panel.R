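#' Panel configuration
#'
#' Describes the antibody panel of a CyTOF run: which acquisition channel
#' carries which marker, and the analytic role of each marker. Core histones
#' (H3, H3.3, H4) are invariant nucleosome proteins used as per-cell
#' normalizers; modifications are the histone marks under study; factors are
#' non-histone proteins (e.g., BCL6) measured alongside.
#'
#' @param channels data.frame with columns `channel_id`, `marker_name`,
#'   `role`; or a list of 3-element vectors in that order. Roles must be one
#'   of `r paste(.panel_roles, collapse = ", ")`.
#' @param sample_key name of the column (or keyword) holding each event's
#'   sample/genotype label. Default `"sample"`.
#' @return an object of class `panel_config`.
#' @examples
#' panel_config(data.frame(
#'   channel_id = c("Yb176Di", "Er167Di"),
#'   marker_name = c("H3", "H3K27me3"),
#'   role = c("core_histone", "modification")))
#' @export
panel_config <- function(channels, sample_key = "sample") {
  if (is.list(channels) && !is.data.frame(channels)) {
    channels <- do.call(rbind, lapply(channels, function(ch) {
      data.frame(channel_id = ch[[1]], marker_name = ch[[2]], role = ch[[3]],
                 stringsAsFactors = FALSE)
    }))
  }
  need <- c("channel_id", "marker_name", "role")
  if (!all(need %in% names(channels)))
    stopf("panel channels need columns: %s", paste(need, collapse = ", "))
  channels <- channels[, need]
  channels[] <- lapply(channels, as.character)
  bad <- setdiff(unique(channels$role), .panel_roles)
  if (length(bad))
    stopf("unknown panel role(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(.panel_roles, collapse = ", "))
  if (anyDuplicated(channels$marker_name))
    stopf("duplicate marker_name in panel: %s",
          paste(unique(channels$marker_name[duplicated(channels$marker_name)]),
                collapse = ", "))
  structure(list(channels = channels, sample_key = sample_key),
            class = "panel_config")
}

.panel_roles <- c("core_histone", "modification", "factor", "cell_cycle",
                  "viability", "barcode", "ignore")

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("panel_config: %d channels (sample key '%s')\n",
              nrow(x$channels), x$sample_key))
  tab <- table(factor(x$channels$role, levels = .panel_roles))
  tab <- tab[tab > 0]
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Marker names of a given role
#'
#' @param panel a [panel_config()].
#' @param role one or more roles to select.
#' @return character vector of marker names.
#' @export
panel_markers <- function(panel, role = .panel_roles) {
  stopifnot(inherits(panel, "panel_config"))
  panel$channels$marker_name[panel$channels$role %in% role]
}

# Validate a panel for normalization use: needs >= 1 core-histone channel.
check_core_histones <- function(panel, required = NULL) {
  ch <- panel_markers(panel, "core_histone")
  if (!length(ch))
    stopf("panel has no channel with role 'core_histone'")
  miss <- setdiff(required, ch)
  if (length(miss))
    stopf("required core-histone channel(s) missing from panel: %s",
          paste(miss, collapse = ", "))
  invisible(ch)
}
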