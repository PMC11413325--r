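# Reader/writer for the per-patient XML layout used by CGM study
# distributions: a <patient> root holding one element per channel
# (glucose_level, meal, bolus, basis_heart_rate or acceleration), each a
# flat list of <event> elements with timestamp/value attributes.

.ohio_ts_fmt <- "%d-%m-%Y %H:%M:%S"

ohio_ts <- function(t) format(t, .ohio_ts_fmt, tz = "UTC")

parse_ohio_ts <- function(s) as.POSIXct(s, format = .ohio_ts_fmt, tz = "UTC")

#' Write a patient record as Ohio-style XML
#'
#' Serialises a [patient_record()] to the per-patient XML layout, so the
#' same reader path serves clinical and synthetic data. Missing glucose
#' points are omitted from the file (as a sensor dropout would be); the
#' train/test boundary and activity mode are stored as attributes of the
#' root element.
#'
#' @param record a [patient_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ohio_xml <- function(record, path) {
  doc <- xml2::xml_new_root("patient",
                            id = record$patient_id,
                            cohort = record$cohort,
                            split = ohio_ts(record$split_time),
                            sample_interval = as.character(record$sample_interval),
                            activity_mode = record$activity_mode)
  add_events <- function(parent_name, times, values, value_attr) {
    node <- xml2::xml_add_child(doc, parent_name)
    for (i in seq_along(times)) {
      ev <- xml2::xml_add_child(node, "event")
      xml2::xml_set_attr(ev, "ts", ohio_ts(times[i]))
      xml2::xml_set_attr(ev, value_attr, format(values[i], digits = 12))
    }
  }
  g <- record$glucose[!record$glucose$missing, , drop = FALSE]
  add_events("glucose_level", g$time, g$value, "value")
  add_events("meal", record$carb$time, record$carb$value, "carbs")
  add_events("bolus", record$bolus$time, record$bolus$value, "dose")
  act_name <- if (record$activity_mode == "heart_rate_5min")
    "basis_heart_rate" else "acceleration"
  add_events(act_name, record$activity$time, record$activity$value, "value")
  xml2::write_xml(doc, path)
  invisible(path)
}

# first non-missing attribute among `attrs`, as numeric
event_values <- function(events, attrs) {
  for (a in attrs) {
    v <- xml2::xml_attr(events, a)
    if (!all(is.na(v))) return(as.numeric(v))
  }
  rep(NA_real_, length(events))
}

#' Read an Ohio-style XML patient file
#'
#' Parses the glucose, meal, bolus and activity event streams into a
#' [patient_record()]. The glucose channel is rebuilt on its regular grid:
#' grid timestamps absent from the file become missing points. The reader
#' tolerates the attribute spellings found across releases (`value`,
#' `carbs`, `dose`; `ts` or `ts_begin`) and reports what it matched;
#' unknown elements are ignored with a message. A file without an
#' activity stream yields an empty activity channel with a warning.
#'
#' @param path XML file path.
#' @param quiet suppress per-element log lines.
#' @return a [patient_record()].
#' @export
read_ohio_xml <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed XML: %s",
                                            conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/patient")
  if (is.na(root)) stopf("not an Ohio-style file: no <patient> root")
  known <- c("glucose_level", "meal", "bolus", "basis_heart_rate",
             "acceleration")
  for (nm in setdiff(xml2::xml_name(xml2::xml_children(root)), known))
    if (!quiet) message("ignoring unknown element <", nm, ">")

  grab <- function(elem, attrs) {
    node <- xml2::xml_find_first(root, elem)
    if (is.na(node)) return(NULL)
    ev <- xml2::xml_find_all(node, "event")
    ts <- xml2::xml_attr(ev, "ts")
    if (all(is.na(ts))) ts <- xml2::xml_attr(ev, "ts_begin")
    vals <- event_values(ev, attrs)
    used <- attrs[which(!vapply(attrs, function(a)
      all(is.na(xml2::xml_attr(ev, a))), TRUE))][1]
    if (!quiet && length(ev))
      message(sprintf("<%s>: %d events (attribute '%s')", elem, length(ev),
                      used %||% attrs[1]))
    data.frame(time = parse_ohio_ts(ts), value = vals)
  }

  glu <- grab("glucose_level", c("value", "glucose"))
  if (is.null(glu) || !nrow(glu)) stopf("missing glucose stream in %s", path)
  step <- as.numeric(xml2::xml_attr(root, "sample_interval"))
  if (is.na(step)) {
    d <- diff(as.numeric(glu$time)) / 60
    step <- as.numeric(names(sort(table(d), decreasing = TRUE))[1])
  }
  grid <- seq(min(glu$time), max(glu$time), by = step * 60)
  idx <- match(round(as.numeric(glu$time)), round(as.numeric(grid)))
  value <- rep(NA_real_, length(grid))
  value[idx[!is.na(idx)]] <- glu$value[!is.na(idx)]
  glucose <- data.frame(time = grid, value = value, missing = is.na(value),
                        imputed = FALSE)

  carb <- grab("meal", c("carbs", "value")) %||%
    data.frame(time = grid[0], value = numeric(0))
  bolus <- grab("bolus", c("dose", "value")) %||%
    data.frame(time = grid[0], value = numeric(0))
  hr <- grab("basis_heart_rate", "value")
  accel <- grab("acceleration", "value")
  activity <- hr %||% accel
  mode_attr <- xml2::xml_attr(root, "activity_mode")
  activity_mode <- if (!is.na(mode_attr)) mode_attr else
    if (!is.null(hr)) "heart_rate_5min" else "accel_magnitude_1min"
  if (is.null(activity)) {
    warnf("no activity stream in %s; activity channel is empty", path)
    activity <- data.frame(time = grid[0], value = numeric(0))
  }

  split_attr <- xml2::xml_attr(root, "split")
  split_time <- if (!is.na(split_attr)) parse_ohio_ts(split_attr) else
    grid[length(grid)] + step * 60
  attr_or <- function(a, default) {
    v <- xml2::xml_attr(root, a)
    if (is.na(v)) default else v
  }
  patient_record(
    patient_id = attr_or("id", "unknown"),
    cohort = attr_or("cohort", "unknown"),
    glucose = glucose, carb = carb, bolus = bolus, activity = activity,
    activity_mode = activity_mode, sample_interval = step,
    split_time = split_time)
}
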