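## Daily Mediterranean-diet adherence score (0-30).
##
## Eleven checklist items, each scored 1 point per serving/unit up to a cap:
##   vegetables 0-5, fruits 0-3, food colors 0-6 (1 per distinct color among
##   red/green/yellow/orange/white/purple), olive oil 0-3 (tablespoons),
##   nuts & seeds 0-1, legumes & soy 0-1, yogurt 0-1, whole grains 0-3,
##   water 0-5 (glasses), daily step goal 0-1, exercise 0-1.
## Fractional servings are floored: the rubric counts whole servings.

.MED_COLORS <- c("red", "green", "yellow", "orange", "white", "purple")

.MED_CAPS <- c(vegetables = 5L, fruits = 3L, food_colors = 6L,
               olive_oil = 3L, nuts_seeds = 1L, legumes_soy = 1L,
               yogurt = 1L, whole_grains = 3L, water = 5L,
               step_goal = 1L, exercise = 1L)

.parseColors <- function(x) {
    if (is.null(x) || length(x) == 0L) return(character(0))
    if (length(x) == 1L && (is.na(x) || !nzchar(trimws(x)))) return(character(0))
    if (length(x) == 1L && grepl(";", x, fixed = TRUE))
        x <- strsplit(x, ";", fixed = TRUE)[[1]]
    x <- tolower(trimws(x))
    x <- x[nzchar(x)]
    bad <- setdiff(x, .MED_COLORS)
    if (length(bad))
        stop("unknown food color label(s): ", paste(bad, collapse = ", "))
    unique(x)
}

.cappedCount <- function(value, cap, item) {
    if (is.na(value)) value <- 0
    if (value < 0)
        stop("negative count for '", item, "'")
    min(floor(value), cap)
}

#' Score one day of the daily MED adherence questionnaire
#'
#' Computes the daily Mediterranean-diet adherence score (0-30) from a single
#' day's checklist record: counted items earn 1 point per serving up to their
#' cap, color diversity earns 1 point per distinct food color (of the six
#' scored colors), nuts/legumes/yogurt are binary (any serving = 1 point),
#' and the daily-step-goal and exercise flags are 1 point each.
#'
#' @param vegetables,fruits,olive_oil_tbsp,whole_grains,water_glasses
#'   non-negative serving/unit counts (fractional values are floored).
#' @param food_colors character vector of food colors consumed, or a single
#'   semicolon-separated string; allowed labels: red, green, yellow, orange,
#'   white, purple.
#' @param nuts_seeds,legumes_soy,yogurt serving counts; any positive count
#'   scores the single available point.
#' @param step_goal_met,exercised logical flags (1 point each).
#' @return A list with the 11 per-component point values and \code{total}
#'   (integer in 0..30).
#' @examples
#' scoreDay(vegetables = 2, fruits = 1,
#'          food_colors = c("red", "green", "white"),
#'          olive_oil_tbsp = 1, legumes_soy = 1, yogurt = 1,
#'          whole_grains = 2, water_glasses = 4, exercised = TRUE)$total
#' @export
scoreDay <- function(vegetables = 0, fruits = 0, food_colors = character(0),
                     olive_oil_tbsp = 0, nuts_seeds = 0, legumes_soy = 0,
                     yogurt = 0, whole_grains = 0, water_glasses = 0,
                     step_goal_met = FALSE, exercised = FALSE) {
    colors <- .parseColors(food_colors)
    comp <- c(
        vegetables   = .cappedCount(vegetables, .MED_CAPS[["vegetables"]],
                                    "vegetables"),
        fruits       = .cappedCount(fruits, .MED_CAPS[["fruits"]], "fruits"),
        food_colors  = length(colors),
        olive_oil    = .cappedCount(olive_oil_tbsp, .MED_CAPS[["olive_oil"]],
                                    "olive_oil_tbsp"),
        nuts_seeds   = .cappedCount(nuts_seeds, .MED_CAPS[["nuts_seeds"]],
                                    "nuts_seeds"),
        legumes_soy  = .cappedCount(legumes_soy, .MED_CAPS[["legumes_soy"]],
                                    "legumes_soy"),
        yogurt       = .cappedCount(yogurt, .MED_CAPS[["yogurt"]], "yogurt"),
        whole_grains = .cappedCount(whole_grains, .MED_CAPS[["whole_grains"]],
                                    "whole_grains"),
        water        = .cappedCount(water_glasses, .MED_CAPS[["water"]],
                                    "water_glasses"),
        step_goal    = as.integer(isTRUE(as.logical(step_goal_met))),
        exercise     = as.integer(isTRUE(as.logical(exercised))))
    out <- as.list(as.integer(comp))
    names(out) <- names(comp)
    out$total <- as.integer(sum(comp))
    out
}

#' Score a table of daily questionnaire records
#'
#' Applies \code{\link{scoreDay}} to every row of a questionnaire data.frame
#' (one row per subject-day, the format written by \code{\link{writeCohort}}).
#'
#' @param records data.frame with columns \code{subject}, \code{date},
#'   \code{vegetables}, \code{fruits}, \code{food_colors} (semicolon-separated
#'   labels), \code{olive_oil_tbsp}, \code{nuts_seeds}, \code{legumes_soy},
#'   \code{yogurt}, \code{whole_grains}, \code{water_glasses},
#'   \code{step_goal_met}, \code{exercised} (0/1 or logical).
#' @return The input with an added integer \code{med_score} column.
#' @export
scoreTable <- function(records) {
    need <- c("subject", "date", "vegetables", "fruits", "food_colors",
              "olive_oil_tbsp", "nuts_seeds", "legumes_soy", "yogurt",
              "whole_grains", "water_glasses", "step_goal_met", "exercised")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop("questionnaire table missing column(s): ",
             paste(miss, collapse = ", "))
    records$med_score <- vapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        scoreDay(vegetables = r$vegetables, fruits = r$fruits,
                 food_colors = as.character(r$food_colors),
                 olive_oil_tbsp = r$olive_oil_tbsp,
                 nuts_seeds = r$nuts_seeds, legumes_soy = r$legumes_soy,
                 yogurt = r$yogurt, whole_grains = r$whole_grains,
                 water_glasses = r$water_glasses,
                 step_goal_met = r$step_goal_met,
                 exercised = r$exercised)$total
    }, integer(1))
    records
}

#' Per-subject summary of daily adherence scores over a window
#'
#' @param records questionnaire data.frame (scored on the fly if the
#'   \code{med_score} column is absent).
#' @param window optional length-2 vector (inclusive date range, compared as
#'   \code{as.Date}); \code{NULL} uses all records.
#' @return data.frame with one row per subject: \code{subject}, \code{mean},
#'   \code{sd} (sample SD; 0 for a single day), \code{n_days}.
#' @examples
#' q <- data.frame(subject = "a", date = as.Date("2024-01-01") + 0:1,
#'                 vegetables = c(2, 4), fruits = 1, food_colors = "red",
#'                 olive_oil_tbsp = 0, nuts_seeds = 0, legumes_soy = 0,
#'                 yogurt = 0, whole_grains = 0, water_glasses = c(3, 5),
#'                 step_goal_met = FALSE, exercised = FALSE)
#' summarizeScores(q)
#' @export
summarizeScores <- function(records, window = NULL) {
    if (!"med_score" %in% names(records))
        records <- scoreTable(records)
    if (!is.null(window)) {
        d <- as.Date(records$date)
        records <- records[d >= as.Date(window[1]) & d <= as.Date(window[2]), ]
    }
    if (!nrow(records))
        stop("no questionnaire records in the requested window")
    agg <- split(records$med_score, records$subject)
    data.frame(
        subject = names(agg),
        mean = vapply(agg, mean, numeric(1)),
        sd = vapply(agg, function(x) if (length(x) < 2) 0 else sd(x),
                    numeric(1)),
        n_days = vapply(agg, length, integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject change in mean daily adherence score (post minus pre)
#'
#' Computes, for each subject present in both windows, the mean daily score
#' over the intervention window minus the mean over the baseline window —
#' the per-subject quantity correlated against delta abundances downstream.
#'
#' @param records questionnaire data.frame.
#' @param t0Window,tendWindow length-2 inclusive date ranges for the baseline
#'   and intervention windows.
#' @return Named numeric vector of score changes, one entry per subject with
#'   records in both windows; errors if any subject is missing a window.
#' @export
deltaScore <- function(records, t0Window, tendWindow) {
    s0 <- summarizeScores(records, t0Window)
    s1 <- summarizeScores(records, tendWindow)
    only <- c(setdiff(s0$subject, s1$subject), setdiff(s1$subject, s0$subject))
    if (length(only))
        stop("subject(s) missing one window: ", paste(only, collapse = ", "))
    common <- intersect(s0$subject, s1$subject)
    setNames(s1$mean[match(common, s1$subject)] -
             s0$mean[match(common, s0$subject)], common)
}
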