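#' Region set of the action-representation network
#'
#' The seven left-hemisphere regions of interest, in canonical order, with
#' their MNI peak coordinates (mm): occipital pole (OP), motion-sensitive
#' MT/V5, posterior superior temporal sulcus (pSTS), anterior intraparietal
#' sulcus (aIPS), inferior parietal lobule (IPL), ventral premotor cortex
#' (PMv) and primary sensorimotor cortex (S/M1).
#'
#' @return A data.frame with columns `region`, `x`, `y`, `z` (MNI mm).
#' @export
#' @examples
#' region_set()
region_set <- function() {
  data.frame(
    region = c("OP", "MT/V5", "pSTS", "aIPS", "IPL", "PMv", "S/M1"),
    x = c(-22, -50, -50, -38, -56, -58, -40),
    y = c(-100, -72, -64, -42, -18, 6, -20),
    z = c(4, 0, 4, 60, 40, 28, 58),
    stringsAsFactors = FALSE
  )
}

#' Region names in canonical order
#' @return Character vector of length 7.
#' @export
region_names <- function() region_set()$region

#' The eight task condition labels
#'
#' Conditions are the full crossing of Execution/Observation, Hand/No-hand and
#' Clockwise/Counter-clockwise rotation.
#'
#' @return A data.frame with columns `label`, `execution`, `hand`, `direction`.
#' @export
condition_labels <- function() {
  grid <- expand.grid(
    direction = c("CW", "CCW"),
    hand = c(TRUE, FALSE),
    execution = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("execution", "hand", "direction")]
  grid$label <- paste0(
    ifelse(grid$execution, "Exec", "Obs"), "_",
    ifelse(grid$hand, "Hand", "NoHand"), "_",
    grid$direction
  )
  grid[, c("label", "execution", "hand", "direction")]
}

# Decode a vector of condition labels into execution/hand flags.
# Rest volumes (NA label) decode to FALSE/FALSE.
decode_conditions <- function(labels) {
  ref <- condition_labels()
  idx <- match(labels, ref$label)
  data.frame(
    execution = ifelse(is.na(idx), FALSE, ref$execution[idx]),
    hand = ifelse(is.na(idx), FALSE, ref$hand[idx])
  )
}
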