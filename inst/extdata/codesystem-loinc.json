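{
  "concept": [
    {
      "code": "78030-4",
      "display": "Episode of care",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 46236992
        }
      ]
    },
    {
      "code": "LP269965-2",
      "display": "Attending",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 1177391
        }
      ]
    },
    {
      "code": "50984-4",
      "display": "Horovitz index in arterial blood",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 3029943
        }
      ]
    },
    {
      "code": "76531-3",
      "display": "Pressure.max respiratory system airway--on ventilator",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 36306157
        }
      ]
    },
    {
      "code": "76154-4",
      "display": "Airway pressure delta--on ventilator",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 42527138
        }
      ]
    },
    {
      "code": "76248-4",
      "display": "PEEP Respiratory system --on ventilator",
      "property": [
        {
          "code": "omop-id",
          "valueInteger": 21490855
        }
      ]
    }
  ],
  "content": "fragment",
  "id": "loinc",
  "resourceType": "CodeSystem",
  "url": "http://loinc.org",
  "version": "2023"
}
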