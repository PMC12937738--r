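Package: surgsched
Title: Elective Surgery Scheduling with Disruption/Restoration Back-Up Plans
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds nominal operating-room schedules for day-hospital elective
    surgery waiting lists together with a ready-to-deploy restoration schedule
    for every enumerated emergency and no-show scenario.  Patients are assigned
    to days and operating rooms by a mixed-integer linear program that weighs
    clinical urgency and time already spent on the waiting list; back-up plans
    guarantee that an emergency of any modelled length class, arriving at any
    15-minute slot of a protected day, is inserted in the first available
    operating room, and that a last-minute cancellation is covered by a
    pre-designated substitute patient.  Includes a synthetic waiting-list
    instance generator, a warm-start and a sequential matheuristic solution
    procedure, an arithmetic schedule validator independent of the solver, and
    a brute-force oracle for tiny instances.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
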