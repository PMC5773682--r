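#' The 27-food questionnaire panel
#'
#' The default food panel modelled by the synthetic cohort generator and the
#' cross-reactivity analysis: twenty-seven foods organised into the standard
#' questionnaire groups (fruits, legumes/grains, nuts, vegetables/mushrooms,
#' eggs/dairy, meats, fish, shellfish). Group membership drives the shared
#' liability component of the generator and hence the block structure of the
#' cross-reactivity matrix.
#'
#' @return data.frame with columns `food` and `group` (27 rows).
#' @examples
#' table(food_panel()$group)
#' @export
food_panel <- function() {
  data.frame(
    food = c(
      "apple", "peach", "kiwi", "banana", "orange", "melon", "strawberry",
      "soybean", "buckwheat", "wheat",
      "peanut", "walnut", "almond", "cashew",
      "chinese_yam", "tomato",
      "egg", "milk",
      "beef", "pork", "chicken",
      "mackerel", "salmon", "sardine",
      "shrimp", "crab", "squid"
    ),
    group = c(
      rep("fruit", 7),
      rep("legume_grain", 3),
      rep("nut", 4),
      rep("vegetable_mushroom", 2),
      rep("egg_dairy", 2),
      rep("meat", 3),
      rep("fish", 3),
      rep("shellfish", 3)
    ),
    stringsAsFactors = FALSE
  )
}

#' Default HLA allele frequency spectra
#'
#' Control-population two-field allele frequency spectra for HLA-DRB1,
#' HLA-DQB1 and HLA-DPB1 used as the generator defaults. These are the
#' reported control-arm allele frequencies of a Japanese female cohort;
#' whatever probability mass the reported spectrum does not account for is
#' assigned to a pooled remainder allele coded "99:99".
#'
#' @return Named list (`DRB1`, `DQB1`, `DPB1`) of named numeric vectors;
#'   each vector sums to 1.
#' @examples
#' sapply(hla_default_freqs(), sum)
#' @export
hla_default_freqs <- function() {
  drb1 <- c(
    "09:01" = 0.148, "04:05" = 0.131, "15:02" = 0.107, "08:03" = 0.082,
    "15:01" = 0.077, "13:02" = 0.070, "01:01" = 0.060, "08:02" = 0.045,
    "04:06" = 0.036, "12:01" = 0.035, "04:03" = 0.034, "14:54" = 0.031,
    "11:01" = 0.027, "12:02" = 0.020, "14:05" = 0.020, "14:06" = 0.016,
    "14:03" = 0.015, "04:10" = 0.015, "04:01" = 0.009, "16:02" = 0.008,
    "13:01" = 0.006
  )
  dqb1 <- c(
    "06:01" = 0.185, "03:03" = 0.160, "04:01" = 0.131, "03:01" = 0.115,
    "03:02" = 0.101, "06:02" = 0.072, "06:04" = 0.064, "05:01" = 0.063,
    "05:03" = 0.040, "04:02" = 0.035, "05:02" = 0.023, "06:03" = 0.005
  )
  dpb1 <- c(
    "05:01" = 0.392, "02:01" = 0.247, "04:02" = 0.100, "09:01" = 0.095,
    "03:01" = 0.054, "04:01" = 0.050, "02:02" = 0.028, "13:01" = 0.018,
    "14:01" = 0.009, "19:01" = 0.006, "06:01" = 0.001
  )
  pad <- function(x) {
    rem <- 1 - sum(x)
    if (rem > 1e-12) x <- c(x, "99:99" = rem)
    x / sum(x)
  }
  list(DRB1 = pad(drb1), DQB1 = pad(dqb1), DPB1 = pad(dpb1))
}
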