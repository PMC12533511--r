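{
  "concept": [
    {
      "code": "FA-ZB-ITS",
      "display": "Physician with intensive care specialist certification"
    },
    {
      "code": "TAGESZIEL",
      "display": "Setting daily care objective"
    },
    {
      "code": "BPS",
      "display": "Behavioral Pain Scale"
    },
    {
      "code": "CAM-ICU",
      "display": "Confusion assessment method for intensive care"
    },
    {
      "code": "ICDSC",
      "display": "Intensive care delirium screening checklist"
    },
    {
      "code": "tvpibw",
      "display": "Tidal volume/ideal body weight (ARDSnet)"
    }
  ],
  "content": "fragment",
  "id": "divi-qi-s",
  "resourceType": "CodeSystem",
  "url": "https://www.divi.de/fhir/CodeSystem/divi-qi-s",
  "version": "2023"
}
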