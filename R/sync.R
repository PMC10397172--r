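#' Teacher-authoritative synchronized playback protocol
#'
#' A teacher creates a room, students join with its code, and from then on
#' playback is controlled exclusively by the teacher: every control action
#' (play, pause, seek, speed, sections-only mode, shared pointer) becomes a
#' sequenced message broadcast to the room. Student state is a pure fold
#' over the message sequence ordered by `seq`, so any delivery order with
#' the same messages yields the same state; students have no API that
#' mutates shared state, making teacher authority structural.
#'
#' @name sync
NULL

# 32-symbol alphabet without the ambiguous 0/O and 1/I
.room_alphabet <- strsplit("23456789ABCDEFGHJKLMNPQRSTUVWXYZ", "")[[1]]
.room_len <- 6L
.sync_version <- "1.0"
.speeds <- c(1, 2, 4, 8)
.commands <- c("play", "pause", "seek", "speed", "mode", "pointer")

#' Create a room code
#'
#' Six characters drawn from an unambiguous uppercase+digit alphabet
#' (no 0/O/1/I). Pass a seed for reproducible codes in tests.
#'
#' @param seed optional integer seed
#' @return a room code string
#' @export
create_room <- function(seed = NULL) {
  draw <- if (is.null(seed)) sample(32L, .room_len, replace = TRUE)
          else { rng <- .seeded_rng(seed); pmin(floor(rng(.room_len) * 32) + 1, 32) }
  paste(.room_alphabet[draw], collapse = "")
}

#' Is this a well-formed room code?
#'
#' @param code candidate string
#' @return logical
#' @export
is_room_code <- function(code) {
  grepl("^[23456789ABCDEFGHJKLMNPQRSTUVWXYZ]{6}$", code)
}

#' Construct a sync message
#'
#' @param room room code
#' @param seq strictly increasing message number within the room
#' @param command one of play, pause, seek, speed, mode, pointer
#' @param t seek target in seconds (command `"seek"`)
#' @param speed playback speed in \{1, 2, 4, 8\} (command `"speed"`)
#' @param mode `"full"` or `"sections"` (command `"mode"`)
#' @param pointer `list(x =, y =, visible =)` (command `"pointer"`)
#' @param issued_at wall-clock seconds when the teacher issued the command
#' @return a `sync_message`
#' @export
sync_message <- function(room, seq, command, t = NULL, speed = NULL,
                         mode = NULL, pointer = NULL, issued_at = 0) {
  if (!is_room_code(room)) .abort("malformed room code", "bad_room")
  if (!command %in% .commands)
    .abort(sprintf("unknown command '%s'", command), "bad_command")
  if (command == "seek" && (is.null(t) || t < 0))
    .abort("seek requires a non-negative time", "bad_message")
  if (command == "speed" && (is.null(speed) || !speed %in% .speeds))
    .abort("speed must be one of 1, 2, 4, 8", "bad_speed")
  if (command == "mode" && (is.null(mode) || !mode %in% c("full", "sections")))
    .abort("mode must be \"full\" or \"sections\"", "bad_message")
  if (command == "pointer" &&
      (is.null(pointer) || !all(c("x", "y", "visible") %in% names(pointer))))
    .abort("pointer requires x, y and visible", "bad_message")
  if (!is.null(pointer))
    pointer <- list(x = as.numeric(pointer$x), y = as.numeric(pointer$y),
                    visible = isTRUE(pointer$visible))
  structure(list(version = .sync_version, room = room, seq = as.integer(seq),
                 command = command,
                 t = if (is.null(t)) NULL else as.numeric(t),
                 speed = if (is.null(speed)) NULL else as.numeric(speed),
                 mode = mode, pointer = pointer,
                 issued_at = as.numeric(issued_at)),
            class = "sync_message")
}

#' Encode / decode sync messages as JSON
#'
#' `decode_message(encode_message(m))` is the identity; decoding validates
#' the schema version, command and arguments (e.g. `speed(3)` is rejected).
#'
#' @param msg a `sync_message`
#' @param json a JSON string
#' @return `encode_message`: JSON string; `decode_message`: a `sync_message`
#' @export
encode_message <- function(msg) {
  # digits = I(17): doubles survive the wire bit-exactly
  as.character(jsonlite::toJSON(
    Filter(Negate(is.null), unclass(msg)), auto_unbox = TRUE, digits = I(17)))
}

#' @rdname encode_message
#' @export
decode_message <- function(json) {
  doc <- tryCatch(jsonlite::parse_json(json),
                  error = function(e) .abort("malformed message document", "bad_message"))
  if (!identical(doc$version, .sync_version))
    .abort("unknown message schema version", "bad_version")
  for (f in c("room", "seq", "command"))
    if (is.null(doc[[f]])) .abort(sprintf("message missing '%s'", f), "bad_message")
  ptr <- doc$pointer
  if (!is.null(ptr)) ptr <- list(x = ptr$x, y = ptr$y, visible = isTRUE(ptr$visible))
  sync_message(doc$room, doc$seq, doc$command, t = doc$t, speed = doc$speed,
               mode = doc$mode, pointer = ptr, issued_at = doc$issued_at %||% 0)
}

#' Playback state
#'
#' @param room room code
#' @param duration video duration in seconds
#' @return a `playback_state`: paused at 0, speed 1, full mode, hidden pointer
#' @export
playback_state <- function(room, duration) {
  structure(list(room = room, duration = duration, playing = FALSE,
                 position = 0, speed = 1, mode = "full",
                 pointer = list(x = 0, y = 0, visible = FALSE),
                 last_seq = 0L),
            class = "playback_state")
}

#' Apply one sync message to a playback state
#'
#' Pure single-step transition: messages whose `seq` is not greater than
#' `last_seq` are ignored (the teacher is the single writer, so
#' last-writer-wins by `seq` is deterministic); a room mismatch is an error.
#'
#' @param state a `playback_state`
#' @param msg a `sync_message`
#' @return the updated `playback_state`
#' @export
apply_message <- function(state, msg) {
  if (!identical(state$room, msg$room))
    .abort("message for a different room", "room_mismatch")
  if (msg$seq <= state$last_seq) return(state)
  switch(msg$command,
    play = { state$playing <- TRUE },
    pause = { state$playing <- FALSE },
    seek = { state$position <- min(max(msg$t, 0), state$duration) },
    speed = { state$speed <- msg$speed },
    mode = { state$mode <- msg$mode },
    pointer = { state$pointer <- msg$pointer })
  state$last_seq <- msg$seq
  state
}

#' Advance playback position between messages
#'
#' Position advances only via the local clock while playing; messages are
#' the only mutators of the shared fields.
#'
#' @param state a `playback_state`
#' @param dt_wall elapsed wall-clock seconds
#' @return the updated state
#' @export
advance_position <- function(state, dt_wall) {
  if (state$playing)
    state$position <- min(state$position + dt_wall * state$speed, state$duration)
  state
}

#' Sync client with out-of-order delivery resolution
#'
#' Students receive broadcast messages over a network, possibly out of
#' order. The client buffers messages arriving ahead of sequence and
#' applies them in `seq` order, so any arrival order of the same messages
#' produces the same state; duplicates and stale messages are dropped.
#'
#' @param room room code
#' @param duration video duration in seconds
#' @return a `sync_client`
#' @export
sync_client <- function(room, duration) {
  structure(list(state = playback_state(room, duration),
                 pending = list()),
            class = "sync_client")
}

#' @rdname sync_client
#' @param client a `sync_client`
#' @param msg an arriving `sync_message`
#' @export
client_ingest <- function(client, msg) {
  if (msg$seq <= client$state$last_seq) return(client)
  client$pending[[as.character(msg$seq)]] <- msg
  repeat {
    nxt <- as.character(client$state$last_seq + 1L)
    if (is.null(client$pending[[nxt]])) break
    client$state <- apply_message(client$state, client$pending[[nxt]])
    client$pending[[nxt]] <- NULL
  }
  client
}

#' Record / replay a teacher session
#'
#' Sessions are logged as JSON-lines (one encoded message per line) and can
#' be replayed deterministically into a fresh client.
#'
#' @param msgs list of `sync_message`
#' @param path JSONL file path
#' @return `record_session`: the path, invisibly; `load_session`: list of
#'   messages; `replay_session`: the final `playback_state` (with attribute
#'   `"trace"`, the state after each applied message)
#' @export
record_session <- function(msgs, path) {
  writeLines(vapply(msgs, encode_message, character(1)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname record_session
#' @export
load_session <- function(path) {
  lapply(readLines(path, warn = FALSE), decode_message)
}

#' @rdname record_session
#' @param duration video duration for the replay state
#' @export
replay_session <- function(msgs, duration) {
  if (is.character(msgs) && length(msgs) == 1L && file.exists(msgs))
    msgs <- load_session(msgs)
  cl <- sync_client(msgs[[1]]$room, duration)
  trace <- vector("list", length(msgs))
  for (i in seq_along(msgs)) {
    cl <- client_ingest(cl, msgs[[i]])
    trace[[i]] <- cl$state
  }
  structure(cl$state, trace = trace)
}
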