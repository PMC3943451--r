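# Instrument definition: the item roster of the emulated disability survey.

#' Default item bank for the emulated disability survey
#'
#' Returns the instrument roster used throughout the package: 42 biological
#' health items (difficulty carrying out activities *without* technical or
#' personal assistance) and 31 lived health items (difficulty *with*
#' assistance taken into account), each rated on a 4-category ordinal scale
#' (1 = no/little difficulty, 2 = moderate, 3 = severe, 4 = cannot do).
#' The roster covers seven activity domains; the five Sensory items per form
#' exist only to be removed at preprocessing, because vision and hearing
#' items do not distinguish capacity from performance. Lived items are
#' administered only to respondents who use technical or personal
#' assistance; two items (driving, menstrual care) apply only to a subgroup.
#'
#' @param version label stored on the bank, default `"edad-2008-emulation"`.
#' @return An object of class `item_bank`: a data frame with columns
#'   `item_id`, `label`, `domain`, `form` (`"biological"` or `"lived"`),
#'   `n_raw_categories` (always 4), `administration_rule` (`"always"`,
#'   `"assisted_only"` or `"subgroup_only"`), and `counterpart_id` (for a
#'   lived item, the biological item sharing its label; `NA` otherwise).
#' @examples
#' bank <- default_item_bank()
#' table(bank$form)
#' @export
default_item_bank <- function(version = "edad-2008-emulation") {
  r <- function(num, stem, label, domain, bio_rule = "always",
                lived = TRUE, lived_rule = "assisted_only") {
    bio_id <- sprintf("%s_%d_2", stem, num)
    out <- data.frame(
      item_id = bio_id, label = label, domain = domain, form = "biological",
      n_raw_categories = 4L, administration_rule = bio_rule,
      counterpart_id = NA_character_, stringsAsFactors = FALSE)
    if (lived) {
      out <- rbind(out, data.frame(
        item_id = sprintf("%s_%d_3b", stem, num), label = label,
        domain = domain, form = "lived", n_raw_categories = 4L,
        administration_rule = lived_rule, counterpart_id = bio_id,
        stringsAsFactors = FALSE))
    }
    out
  }
  com <- "Communication"
  apr <- "Learning"
  mov <- "Mobility"
  aut <- "Self-care"
  vdm <- "Home Life"
  int <- "Interaction"
  rows <- list(
    r(8L,  "COM", "Speak intelligibly or utter coherent phrases?", com),
    r(9L,  "COM", "Understand what other persons say to you?", com),
    r(10L, "COM", "Understand and express yourself in writing?", com, lived = FALSE),
    r(11L, "COM", "Understand and express yourself via gestures, symbols, illustrations or sounds?", com, lived = FALSE),
    r(12L, "COM", "Hold a dialogue and exchange ideas with one or more persons?", com, lived = FALSE),
    r(13L, "COM", "Use the telephone or other devices or communication techniques?", com),
    r(14L, "APR", "Hold a gaze or pay attention when listening?", apr, lived = FALSE),
    r(15L, "APR", "Learn to perform simple tasks?", apr, lived = FALSE),
    r(16L, "APR", "Perform simple tasks?", apr),
    r(17L, "APR", "Perform complex tasks?", apr),
    r(18L, "MOV", "Change posture?", mov),
    r(19L, "MOV", "Keep the body in the same position?", mov),
    r(20L, "MOV", "Walk and move around the home?", mov),
    r(21L, "MOV", "Walk or move outside the home?", mov),
    r(22L, "MOV", "Get around via passenger transport?", mov),
    r(23L, "MOV", "Drive vehicles?", mov, bio_rule = "subgroup_only",
      lived_rule = "subgroup_only"),
    r(24L, "MOV", "Lift or carry objects?", mov),
    r(25L, "MOV", "Handle and move objects?", mov),
    r(26L, "MOV", "Lift or carry small objects?", mov),
    r(27L, "AUT", "Wash or dry different body parts?", aut),
    r(28L, "AUT", "Perform basic grooming?", aut),
    r(29L, "AUT", "Carry out activities related to urination?", aut),
    r(30L, "AUT", "Carry out activities related to defecation?", aut),
    r(31L, "AUT", "Carry out activities related to menstrual care?", aut,
      bio_rule = "subgroup_only", lived_rule = "subgroup_only"),
    r(32L, "AUT", "Dress or undress?", aut),
    r(33L, "AUT", "Eat and drink?", aut),
    r(34L, "AUT", "Follow medical prescriptions?", aut),
    r(35L, "AUT", "Avoid dangerous situations?", aut),
    r(36L, "VDOM", "Do shopping?", vdm),
    r(37L, "VDOM", "Prepare meals?", vdm),
    r(38L, "VDOM", "Carry out housework?", vdm),
    r(39L, "INTER", "Show to other persons affection, respect or transmit feelings?", int, lived = FALSE),
    r(40L, "INTER", "Relate to strangers?", int, lived = FALSE),
    r(41L, "INTER", "Initiate and maintain relations with subordinates, peers or superiors?", int, lived = FALSE),
    r(42L, "INTER", "Initiate and maintain relations with friends, neighbours, acquaintances or colleagues?", int, lived = FALSE),
    r(43L, "INTER", "Initiate and maintain family relations?", int, lived = FALSE),
    r(44L, "INTER", "Initiate and maintain intimate or sexual relations?", int, lived = FALSE)
  )
  roster <- do.call(rbind, rows)
  # Sensory placeholders: the survey had vision and hearing questions that
  # are dropped at preprocessing because they do not separate the two forms.
  sens <- do.call(rbind, lapply(1:5, function(k) {
    bio_id <- sprintf("SEN_%d_2", k)
    rbind(
      data.frame(item_id = bio_id,
                 label = sprintf("Sensory placeholder %d (vision/hearing)?", k),
                 domain = "Sensory", form = "biological",
                 n_raw_categories = 4L, administration_rule = "always",
                 counterpart_id = NA_character_, stringsAsFactors = FALSE),
      data.frame(item_id = sprintf("SEN_%d_3b", k),
                 label = sprintf("Sensory placeholder %d (vision/hearing)?", k),
                 domain = "Sensory", form = "lived",
                 n_raw_categories = 4L, administration_rule = "assisted_only",
                 counterpart_id = bio_id, stringsAsFactors = FALSE))
  }))
  bank <- rbind(roster, sens)
  rownames(bank) <- NULL
  structure(bank, version = version, class = c("item_bank", "data.frame"))
}

validate_item_bank <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (anyDuplicated(bank$item_id))
    stop_invalid("bank", "item ids must be unique")
  bad <- !bank$form %in% c("biological", "lived")
  if (any(bad)) stop_invalid("bank", "form must be biological or lived")
  lived <- bank[bank$form == "lived", ]
  cp <- match(lived$counterpart_id, bank$item_id)
  if (anyNA(cp))
    stop_invalid("bank", "every lived item needs a biological counterpart")
  if (!all(bank$label[cp] == lived$label))
    stop_invalid("bank", "lived items must share their counterpart's label")
  invisible(bank)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank '%s'> %d items (%d biological, %d lived)\n",
              attr(x, "version"), nrow(x),
              sum(x$form == "biological"), sum(x$form == "lived")))
  cat("domains:", paste(unique(x$domain), collapse = ", "), "\n")
  invisible(x)
}

bank_items <- function(bank, form, include_sensory = TRUE) {
  sel <- bank$form == form
  if (!include_sensory) sel <- sel & bank$domain != "Sensory"
  bank$item_id[sel]
}

#' Serialize / read an item bank as JSON
#'
#' @param bank an `item_bank`.
#' @param path file path.
#' @return `read_item_bank()` returns the `item_bank`.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  jsonlite::write_json(
    list(version = attr(bank, "version"),
         items = as.data.frame(bank)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(obj$items, stringsAsFactors = FALSE)
  items$n_raw_categories <- as.integer(items$n_raw_categories)
  items$counterpart_id <- as.character(items$counterpart_id)
  items$counterpart_id[items$counterpart_id == "NULL"] <- NA_character_
  bank <- structure(items, version = obj$version,
                    class = c("item_bank", "data.frame"))
  validate_item_bank(bank)
  bank
}
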