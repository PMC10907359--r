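{"original_event":{"epidemic_name":["covid-19","epidemic","pneumonia"],"infections":["cases","positive"],"virus":["asymptomatic"],"status":["death","virus_parameters"],"policies":["close_loop","initial_screening"]},"derived_event":{"event_name":["fire","transfer"],"people":["experts","out_of_province"],"materials":["wire_board"],"environment":["xinjiang","time"],"response":["detection","prevention"],"consequence":["injured"]},"public_prediction":{"residence":["mass","public"],"vulnerable_groups":["the_elderly"],"measures":["government","current"],"projections":["according_to","other_provinces"],"environment":["community","neighborhood"],"service":["designated_hospitals","medical_observation"],"livelihood":["high_risk","local"],"management":["recovery","homestay"]},"public_expectation":{"object":["state","country"],"condition":["public_health","economy"],"requirement":["optimization","development"],"desires":["release","scientific"]}}
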