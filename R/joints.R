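#' The 32-joint Azure-Kinect-style skeleton
#'
#' Joint names of the hierarchical 32-joint skeleton emitted by Azure Kinect
#' (k4a) body tracking, in canonical serialization order. The detector only
#' consumes a subset (ears, eyes, nose, head, neck, thumbs, pelvis), but
#' streams carry the full skeleton.
#'
#' @return Character vector of the 32 joint names.
#' @export
#' @examples
#' length(azure_kinect_joints())
azure_kinect_joints <- function() K4A_JOINTS

K4A_JOINTS <- c(
  "pelvis", "spine_navel", "spine_chest", "neck",
  "clavicle_l", "shoulder_l", "elbow_l", "wrist_l", "hand_l", "handtip_l", "thumb_l",
  "clavicle_r", "shoulder_r", "elbow_r", "wrist_r", "hand_r", "handtip_r", "thumb_r",
  "hip_l", "knee_l", "ankle_l", "foot_l",
  "hip_r", "knee_r", "ankle_r", "foot_r",
  "head", "nose", "eye_l", "eye_r", "ear_l", "ear_r"
)

#' Contact-area and event label vocabularies
#'
#' `contact_areas()` returns the six face contact classes the classifier can
#' emit. `event_labels()` adds the two labels that only occur in evaluation
#' data: `occlusion` (ground-truth face-occlusion events, which the classifier
#' by design never detects) and `no_detection` (a truth event the classifier
#' missed entirely).
#'
#' @return Character vector of labels.
#' @export
#' @examples
#' contact_areas()
contact_areas <- function() {
  c("mouth_nose", "right_eye", "left_eye", "right_ear", "left_ear", "low_risk")
}

#' @rdname contact_areas
#' @export
event_labels <- function() c(contact_areas(), "occlusion", "no_detection")

# 7-way (pre-merge) area vocabulary, in tie-break priority order
AREA7 <- c("nose", "mouth", "right_eye", "left_eye", "right_ear", "left_ear")
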