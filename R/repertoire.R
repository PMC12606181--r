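# Behavioural repertoire and risk tiers.
#
# The repertoire is closed: one no-contact proximity label recorded by
# nearest-neighbour scan sampling, plus five all-occurrence contact
# behaviours. Tiers order behaviours by presumed risk/investment.

.REPERTOIRE <- c("proximity", "shoulder_contact", "allopreen", "beak_touch",
                 "allofeed", "copulation")

.TIER_LEVELS <- c("LOW", "MODERATE", "HIGH")

.TIER_MAP <- c(
  proximity        = "LOW",
  shoulder_contact = "MODERATE",
  allopreen        = "MODERATE",
  beak_touch       = "MODERATE",
  allofeed         = "HIGH",
  copulation       = "HIGH"
)

#' Behaviour repertoire
#'
#' The closed set of behaviour labels the pipeline accepts: `proximity`
#' (no-contact nearest-neighbour scan) and five affiliative contact
#' behaviours (`shoulder_contact`, `allopreen`, `beak_touch`, `allofeed`,
#' `copulation`).
#'
#' @return Character vector of behaviour labels.
#' @export
behavior_repertoire <- function() .REPERTOIRE

#' Risk tier levels
#'
#' @return Character vector `c("LOW", "MODERATE", "HIGH")`, in escalation
#'   order.
#' @export
risk_tiers <- function() .TIER_LEVELS

#' Map behaviours to risk tiers
#'
#' Deterministic, total mapping over the repertoire: `proximity` is LOW;
#' `shoulder_contact`, `allopreen` and `beak_touch` are MODERATE;
#' `allofeed` and `copulation` are HIGH.
#'
#' @param behavior Character vector of behaviour labels.
#' @return Ordered factor of tiers (`LOW < MODERATE < HIGH`), same length as
#'   `behavior`.
#' @examples
#' tier_of(c("allopreen", "proximity", "copulation"))
#' @export
tier_of <- function(behavior) {
  unknown <- setdiff(unique(behavior), names(.TIER_MAP))
  if (length(unknown) > 0L) {
    stop("behaviour(s) outside the repertoire: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  factor(unname(.TIER_MAP[behavior]), levels = .TIER_LEVELS, ordered = TRUE)
}
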