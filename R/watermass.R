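#' @title Chukchi shelf water-mass classification
#' @description
#' T/S box classification of Chukchi Sea water masses (winter waters,
#' Pacific summer waters, meltwaters, river water, Atlantic Water) and the
#' partition of surface records into southern/northern regions and
#' ACW / non-ACW groups used for the regional flux statistics.
#' @name watermass
NULL

#' Water-mass definition table
#'
#' T/S boxes for the Chukchi shelf water masses. All inequalities are
#' strict, so a sample lying exactly on a printed boundary matches no box
#' and is labelled `OTHER` unless a neighbouring box includes it. Where
#' River Water and Late-season Melt Water overlap (T > 8, S < 30) River
#' Water wins via the `priority` column. Atlantic Water is only reachable
#' when depth context says the sample is from below the shelf
#' (`requires_depth`), since it does not surface on the shelf.
#'
#' @return A tibble with columns `label`, `t_min`, `t_max`, `s_min`,
#'   `s_max`, `priority`, `requires_depth`. Lower `priority` values are
#'   matched first. Amend this table to explore alternative definitions.
#' @export
water_mass_rules <- function() {
  tibble::tribble(
    ~label,  ~t_min, ~t_max, ~s_min, ~s_max, ~priority, ~requires_depth,
    "AW",      -1.0,    Inf,   33.6,    Inf,        1L,  TRUE,
    "RW",       8.0,    Inf,   -Inf,   30.0,        2L,  FALSE,
    "NVWW",    -Inf,   -1.6,   31.5,    Inf,        3L,  FALSE,
    "RWW",     -1.6,    0.0,   31.5,    Inf,        4L,  FALSE,
    "ACW",      3.0,    Inf,   30.0,   32.0,        5L,  FALSE,
    "BSW",      0.0,    3.0,   30.0,   33.6,        6L,  FALSE,
    "BSW",      3.0,    Inf,   32.0,   33.6,        7L,  FALSE,
    "ESMW",    -Inf,    0.0,   -Inf,   31.5,        8L,  FALSE,
    "LSMW",     0.0,    Inf,   -Inf,   30.0,        9L,  FALSE
  )
}

#' Classify water masses from temperature and salinity
#'
#' @param temperature In-situ temperature, degC.
#' @param salinity Practical salinity.
#' @param below_shelf Logical (recycled): is the sample from below the
#'   shelf (> ~150 m)? Only then can the Atlantic Water box match.
#' @param rules Definition table, see [water_mass_rules()].
#' @return Character vector of labels (`NVWW`, `RWW`, `ACW`, `BSW`,
#'   `ESMW`, `LSMW`, `RW`, `AW` or `OTHER`).
#' @export
#' @examples
#' classify_water_mass(c(-1.7, 5, 1, 9), c(32, 31, 31, 29))
classify_water_mass <- function(temperature, salinity, below_shelf = FALSE,
                                rules = water_mass_rules()) {
  if (any(is.na(temperature)) || any(is.na(salinity)))
    stop("classify_water_mass: NA temperature or salinity", call. = FALSE)
  n <- max(length(temperature), length(salinity))
  temperature <- rep_len(temperature, n)
  salinity <- rep_len(salinity, n)
  below_shelf <- rep_len(below_shelf, n)
  rules <- dplyr::arrange(rules, .data$priority)
  out <- rep("OTHER", n)
  unset <- rep(TRUE, n)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    hit <- unset &
      temperature > r$t_min & temperature < r$t_max &
      salinity > r$s_min & salinity < r$s_max &
      (!r$requires_depth | below_shelf)
    out[hit] <- r$label
    unset <- unset & !hit
  }
  out
}

#' Assign region and water-mass group
#'
#' Splits records at 69.5 degN into southern and northern Chukchi shelf and
#' groups water masses for the flux statistics: `ACW` (Alaskan Coastal
#' Water plus River Water), `nonACW` (Bering Summer Water and the two
#' meltwaters), `winter` (newly-ventilated and remnant winter water);
#' anything else, or records outside the 66-74 degN study domain, is
#' `excluded`.
#'
#' @param lat Latitude, degN.
#' @param label Water-mass label, as from [classify_water_mass()].
#' @return A tibble with columns `region` (`southern`/`northern`) and
#'   `group`.
#' @export
#' @examples
#' assign_region_group(c(68, 70, 75), c("BSW", "RW", "ACW"))
assign_region_group <- function(lat, label) {
  n <- max(length(lat), length(label))
  lat <- rep_len(lat, n)
  label <- rep_len(label, n)
  region <- ifelse(lat < 69.5, "southern", "northern")
  group <- dplyr::case_when(
    lat < 66 | lat > 74 ~ "excluded",
    label %in% c("ACW", "RW") ~ "ACW",
    label %in% c("BSW", "ESMW", "LSMW") ~ "nonACW",
    label %in% c("NVWW", "RWW") ~ "winter",
    TRUE ~ "excluded"
  )
  tibble::tibble(region = region, group = group)
}

#' Label a table of surface records with water mass, region and group
#'
#' Data-frame-first wrapper around [classify_water_mass()] and
#' [assign_region_group()]; appends `water_mass`, `region` and `group`
#' columns.
#'
#' @param data A data frame with temperature, salinity and latitude
#'   columns.
#' @param t,s,lat Column names (tidy-eval) holding temperature, salinity
#'   and latitude; default `sst`, `sss`, `lat`.
#' @return `data` as a tibble with the three label columns appended.
#' @export
label_water_masses <- function(data, t = sst, s = sss, lat = lat) {
  tv <- dplyr::pull(data, {{ t }})
  sv <- dplyr::pull(data, {{ s }})
  latv <- dplyr::pull(data, {{ lat }})
  wm <- classify_water_mass(tv, sv)
  rg <- assign_region_group(latv, wm)
  dplyr::bind_cols(tibble::as_tibble(data),
                   tibble::tibble(water_mass = wm,
                                  region = rg$region, group = rg$group))
}
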