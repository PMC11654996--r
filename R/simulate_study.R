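#' Simulate a long-format pain-measurement table
#'
#' Generates the pain table of one study: for each participant, a
#' randomized four-block session (two sync, two async, via [plan_session()])
#' with pre and post measurements per block, bilaterally, for the Algopeg
#' (0-10 rating at the finger and earlobe) and the Somedic algometer
#' (pressure-pain threshold in kPa at the finger, each value the mean of
#' `n_repetitions` ramp repetitions).
#'
#' Participants get stable baselines (Algopeg rating around 3-5, Somedic
#' threshold around 350 kPa) plus measurement noise. `sync_effect` injects
#' a true analgesic effect of synchronous stimulation, expressed as a
#' post-pre shift in pain sensitivity (negative = less sensitive) applied
#' to sync blocks: useful for power checks; the default 0 matches a null
#' study.
#'
#' @param n_participants Number of participants; default 20.
#' @param sync_effect True sync-condition shift in delta units (Algopeg
#'   points; scaled by 30 kPa per point for Somedic). Default 0.
#' @param seed Integer seed.
#' @param n_repetitions Somedic ramp repetitions averaged per value;
#'   default 3.
#' @return A data frame in the format required by [compute_pain_deltas()].
#' @export
simulate_pain_table <- function(n_participants = 20, sync_effect = 0,
                                seed = NULL, n_repetitions = 3) {
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      plan <- plan_session()$blocks
      base_alg_finger <- runif(1, 2.5, 5.5)
      base_alg_ear <- runif(1, 2.5, 5.5)
      base_som <- rnorm(1, 350, 60)
      for (b in seq_len(nrow(plan))) {
        cond <- plan$condition[b]
        shift <- if (cond == "sync") sync_effect else 0
        for (phase in c("pre", "post")) {
          eff <- if (phase == "post") shift else 0
          for (side in c("left", "right")) {
            alg_f <- clamp01(base_alg_finger + eff + rnorm(1, 0, 0.25), 0, 10)
            alg_e <- clamp01(base_alg_ear + eff + rnorm(1, 0, 0.25), 0, 10)
            som <- base_som - 30 * eff +
              mean(rnorm(n_repetitions, 0, 25))
            rows[[length(rows) + 1L]] <- data.frame(
              participant = p, block = b, condition = cond, phase = phase,
              instrument = c("algopeg", "algopeg", "somedic"),
              site = c("finger", "earlobe", "finger"),
              side = side,
              value = c(round(alg_f * 2) / 2, round(alg_e * 2) / 2,
                        max(som, 50))
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate questionnaire responses
#'
#' Generates SUS, SSQ and per-condition ownership item scores for a usable,
#' well-tolerated setup that fails to induce ownership: SUS items
#' concentrated at 4-5, SSQ items mostly 1 (no symptoms) with occasional
#' 2s, and ownership items floor-skewed (mostly 0-1) in both conditions.
#'
#' @param n_participants Number of participants; default 20.
#' @param seed Integer seed.
#' @return A list with integer matrices `sus` (n x 3, 1-5), `ssq`
#'   (n x 7, 1-4), `ownership_sync` and `ownership_async` (n x 7, 0-6).
#' @export
simulate_questionnaires <- function(n_participants = 20, seed = NULL) {
  with_seed(seed, {
    n <- n_participants
    sus <- matrix(
      sample(3:5, n * 3, replace = TRUE, prob = c(0.08, 0.40, 0.52)),
      nrow = n
    )
    ssq <- matrix(
      sample(1:3, n * 7, replace = TRUE, prob = c(0.85, 0.13, 0.02)),
      nrow = n
    )
    own <- function() {
      matrix(
        sample(0:3, n * 7, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)),
        nrow = n
      )
    }
    list(
      sus = sus, ssq = ssq,
      ownership_sync = own(), ownership_async = own()
    )
  })
}
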