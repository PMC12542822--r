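#' TMT channel design
#'
#' Maps reporter channels to experimental conditions and replicate labels.
#' The default reproduces a 6-plex with three control and three treatment
#' channels (three biological replicates per condition).
#'
#' @param n_per_condition Channels per condition (default 3).
#' @param conditions Two condition labels; the second is the treatment level
#'   whose mean is contrasted against the first.
#' @return A `data.frame` with columns `channel` (1-based reporter index),
#'   `condition` and `replicate`, of class `channel_design`.
#' @examples
#' channel_design()
#' @export
channel_design <- function(n_per_condition = 3L,
                           conditions = c("control", "treatment")) {
  n_per_condition <- .check_count(n_per_condition, "n_per_condition", min = 2L)
  if (length(conditions) != 2L || anyDuplicated(conditions))
    .stop_config("conditions", "must be two distinct labels")
  d <- data.frame(
    channel = seq_len(2L * n_per_condition),
    condition = rep(conditions, each = n_per_condition),
    replicate = rep(seq_len(n_per_condition), 2L),
    stringsAsFactors = FALSE
  )
  class(d) <- c("channel_design", "data.frame")
  d
}

.validate_design <- function(design) {
  req <- c("channel", "condition")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with columns 'channel' and 'condition'",
         call. = FALSE)
  if (anyDuplicated(design$channel))
    stop("design channels must be disjoint", call. = FALSE)
  tab <- table(design$condition)
  if (length(tab) != 2L || any(tab < 2L))
    stop("design needs exactly two conditions with >= 2 channels each",
         call. = FALSE)
  design
}

# Condition labels in contrast order: c(reference, treatment).
.design_levels <- function(design) {
  if (!is.null(attr(design, "levels"))) return(attr(design, "levels"))
  u <- unique(design$condition)
  if ("control" %in% u) u <- c("control", setdiff(u, "control"))
  u
}
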