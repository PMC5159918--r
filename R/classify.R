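#' Organic- vs mineral-soil wetland classification
#'
#' Histosol-derived field rules decide whether a profile represents an
#' organic-soil wetland. A profile is organic when any of:
#'
#' * (a) every horizon down to at least 40 cm was field-identified as
#'   organic (peat, muck, mucky peat) — no mineral horizon intersects
#'   \[0, 40) cm and the profile is described to 40 cm or more;
#' * (b) at least 40 cm of the top 80 cm is organic;
#' * (c) an impenetrable layer lies within the top 40 cm, two-thirds or
#'   more of the described soil thickness is organic, and total mineral
#'   thickness is under 10 cm.
#'
#' Profiles failing all three are mineral. Thresholds are inclusive for
#' "at least" (>= 40 cm) and strict for the mineral cap in rule (c)
#' (< 10 cm). The decision depends only on cumulative organic/mineral
#' thickness, so subdividing any horizon never changes the class.
#'
#' @param profile horizon table for one site with `organic_flag` set on
#'   every horizon.
#' @param impenetrable_depth_cm depth of an impenetrable layer, or `NA`
#'   when none was recorded. Rule (c) applies only when this is < 40 cm.
#' @return `"organic"` or `"mineral"`.
#' @export
classify_soil <- function(profile, impenetrable_depth_cm = NA_real_) {
  if (anyNA(profile$organic_flag)) {
    stop(sprintf("missing organic_flag for site %s: cannot classify",
                 profile$site_id[1]), call. = FALSE)
  }
  top <- profile$top_depth_cm
  bot <- profile$bottom_depth_cm
  organic <- profile$organic_flag
  described <- max(bot)

  thickness_in <- function(lo, hi) {
    pmax(pmin(bot, hi) - pmax(top, lo), 0)
  }

  # (a) organic throughout the top 40 cm
  mineral_above_40 <- any(!organic & top < 40 - 1e-9)
  rule_a <- described >= 40 - 1e-9 && !mineral_above_40

  # (b) >= 40 cm organic within the top 80 cm
  organic_top80 <- sum(thickness_in(0, 80)[organic])
  rule_b <- organic_top80 >= 40 - 1e-9

  # (c) shallow impenetrable layer
  rule_c <- FALSE
  if (!is.na(impenetrable_depth_cm) && impenetrable_depth_cm < 40) {
    organic_total <- sum((bot - top)[organic])
    mineral_total <- sum((bot - top)[!organic])
    rule_c <- organic_total >= (2 / 3) * described - 1e-9 &&
      mineral_total < 10 - 1e-9
  }

  if (rule_a || rule_b || rule_c) "organic" else "mineral"
}

#' Classify every site in a horizon table
#'
#' @param horizons validated horizon table.
#' @param sites optional site table supplying `impenetrable_depth_cm`.
#' @return tibble with `site_id` and `soil_class`.
#' @export
classify_soil_sites <- function(horizons, sites = NULL) {
  profs <- split(tibble::as_tibble(horizons), horizons$site_id)
  imp <- setNames(rep(NA_real_, length(profs)), names(profs))
  if (!is.null(sites)) {
    m <- match(names(profs), sites$site_id)
    imp[] <- sites$impenetrable_depth_cm[m]
  }
  tibble::tibble(
    site_id = names(profs),
    soil_class = vapply(names(profs), function(id) {
      classify_soil(profs[[id]], imp[[id]])
    }, "")
  )
}

#' Blue vs teal carbon type
#'
#' Tidal saline (coastal) wetlands store blue carbon; freshwater inland
#' wetlands store teal carbon. Every site maps to exactly one type.
#'
#' @param tidal_saline logical vector.
#' @return character vector, `"blue"` or `"teal"`.
#' @export
carbon_type <- function(tidal_saline) {
  stopifnot(!anyNA(tidal_saline))
  ifelse(tidal_saline, "blue", "teal")
}
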