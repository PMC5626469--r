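#' Assemble an integrated SCR dataset
#'
#' Combines the state space, trap array, individual detection histories,
#' sexes and auxiliary georeferenced locations into a validated dataset
#' ready for [scr_fit()].  The individual list is augmented to size `M`
#' with all-zero encounter histories; the data-augmentation machinery of
#' the model estimates how many of those correspond to real, unobserved
#' individuals.
#'
#' @param space an [scr_state_space].
#' @param traps an [scr_traps] array.
#' @param detections data frame with columns `individual_id`, `trap_id`,
#'   `occasion` (1-based), one row per binary detection.  Repeated rows for
#'   the same (individual, trap, occasion) collapse to a single detection.
#' @param sexes data frame with columns `individual_id` and `sex`
#'   (`"F"`/`"M"`).  Sex must be known for every observed individual.
#' @param aux optional data frame of auxiliary locations with columns
#'   `individual_id`, `x_km`, `y_km`, `occasion`, `source`
#'   (`"telemetry"` or `"opportunistic"`).  Individuals appearing only here
#'   (never trapped) are retained as observed individuals with all-zero
#'   trap histories and are pinned alive in the model.
#' @param M augmented population size (study default 300).  Must exceed the
#'   number of observed individuals.
#' @return An object of class `scr_data`.
#' @export
scr_data <- function(space, traps, detections, sexes, aux = NULL, M = 300L) {
  stopifnot(inherits(space, "scr_state_space"), inherits(traps, "scr_traps"))
  J <- traps$J; K <- traps$K

  detections <- as.data.frame(detections)
  need <- c("individual_id", "trap_id", "occasion")
  if (!all(need %in% names(detections)))
    stop("detections must have columns individual_id, trap_id, occasion")
  if (!is.null(aux)) {
    aux <- as.data.frame(aux)
    need_aux <- c("individual_id", "x_km", "y_km", "occasion", "source")
    if (!all(need_aux %in% names(aux)))
      stop("aux must have columns individual_id, x_km, y_km, occasion, source")
    bad_src <- setdiff(unique(as.character(aux$source)),
                       c("telemetry", "opportunistic"))
    if (length(bad_src))
      stop(sprintf("aux: unknown source '%s' (expected telemetry or opportunistic)",
                   bad_src[1]))
    if (any(!is.finite(aux$x_km)) || any(!is.finite(aux$y_km)))
      stop("aux coordinates must be finite")
  }

  sexes <- as.data.frame(sexes)
  if (!all(c("individual_id", "sex") %in% names(sexes)))
    stop("sexes must have columns individual_id and sex")
  if (!is.null(aux) && nrow(aux)) {
    known <- unique(c(as.character(detections$individual_id),
                      as.character(sexes$individual_id)))
    bad <- which(!(as.character(aux$individual_id) %in% known))
    if (length(bad))
      stop(sprintf("aux row %d: unknown individual '%s' (auxiliary fixes must belong to identified individuals)",
                   bad[1], as.character(aux$individual_id)[bad[1]]))
  }

  ids <- unique(c(as.character(detections$individual_id),
                  if (!is.null(aux)) as.character(aux$individual_id)))
  n <- length(ids)
  if (M < n)
    stop(sprintf("M = %d is smaller than the number of observed individuals (%d)", M, n))

  # detections -> M x J x K binary array
  y <- array(0L, dim = c(M, J, K))
  if (nrow(detections)) {
    i <- match(as.character(detections$individual_id), ids)
    j <- match(as.character(detections$trap_id), traps$ids)
    if (anyNA(j)) {
      row <- which(is.na(j))[1]
      stop(sprintf("detections row %d: trap_id '%s' not found in the trap array",
                   row, as.character(detections$trap_id)[row]))
    }
    k <- as.integer(detections$occasion)
    if (any(k < 1L | k > K)) {
      row <- which(k < 1L | k > K)[1]
      stop(sprintf("detections row %d: occasion %d outside 1..%d", row, k[row], K))
    }
    off <- which(traps$operation[cbind(j, k)] == 0)
    if (length(off)) {
      stop(sprintf("detections row %d: trap '%s' was not operational in occasion %d",
                   off[1], traps$ids[j[off[1]]], k[off[1]]))
    }
    y[cbind(i, j, k)] <- 1L
  }

  # sexes: 0 = female, 1 = male, NA = unknown (augmented rows)
  sx <- rep(NA_integer_, M)
  m <- match(ids, as.character(sexes$individual_id))
  if (anyNA(m)) {
    miss <- ids[is.na(m)][1]
    stop(sprintf("sex unknown for observed individual '%s' (sex must be known for all observed individuals)", miss))
  }
  lab <- toupper(as.character(sexes$sex)[m])
  if (!all(lab %in% c("F", "M")))
    stop("sexes$sex must be 'F' or 'M'")
  sx[seq_len(n)] <- ifelse(lab == "M", 1L, 0L)

  aux_forced <- rep(FALSE, M)
  aux_records <- NULL
  if (!is.null(aux) && nrow(aux)) {
    ai <- match(as.character(aux$individual_id), ids)
    stopifnot(!anyNA(ai))             # aux ids were included in `ids`
    aux_records <- data.frame(
      individual = ai,
      x = as.numeric(aux$x_km), y = as.numeric(aux$y_km),
      occasion = as.integer(aux$occasion),
      source = as.character(aux$source),
      stringsAsFactors = FALSE
    )
    aux_forced[unique(ai)] <- TRUE
  }

  structure(
    list(space = space, traps = traps,
         y = y, n = n, M = as.integer(M), ids = ids,
         sex = sx, aux_forced = aux_forced,
         aux = aux_records,
         R_tel = if (is.null(aux_records)) 0L else sum(aux_records$source == "telemetry"),
         R_opp = if (is.null(aux_records)) 0L else sum(aux_records$source == "opportunistic")),
    class = "scr_data"
  )
}

#' @export
print.scr_data <- function(x, ...) {
  cat("Integrated SCR dataset\n")
  cat(sprintf("  individuals: %d observed (%d F, %d M), augmented to M = %d\n",
              x$n, sum(x$sex[seq_len(x$n)] == 0L), sum(x$sex[seq_len(x$n)] == 1L), x$M))
  cat(sprintf("  traps: J = %d, occasions: K = %d, detections: %d\n",
              x$traps$J, x$traps$K, sum(x$y)))
  cat(sprintf("  auxiliary fixes: %d telemetry, %d opportunistic (%d individuals)\n",
              x$R_tel, x$R_opp, sum(x$aux_forced)))
  cat(sprintf("  state space: %d pixels at %g km\n",
              x$space$n_pixels, x$space$resolution))
  invisible(x)
}

# subset auxiliary records according to the model's data-source switches
aux_subset <- function(data, use_telemetry, use_opportunistic) {
  if (is.null(data$aux)) return(NULL)
  keep <- (data$aux$source == "telemetry" & use_telemetry) |
          (data$aux$source == "opportunistic" & use_opportunistic)
  if (!any(keep)) return(NULL)
  data$aux[keep, , drop = FALSE]
}
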